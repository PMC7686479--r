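# Genotype container, I/O, QC, allele harmonisation, relatedness, MDS.

#' Construct a genotype matrix
#'
#' @param dosages numeric subjects x variants matrix with values in [0, 2]
#'   (NA marks missing).
#' @param variants data frame with columns id, chrom, pos, ref_allele,
#'   alt_allele, maf, info, missing_rate.
#' @return An object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  req <- c("id", "chrom", "pos", "ref_allele", "alt_allele",
           "maf", "info", "missing_rate")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("variant metadata missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("variant metadata rows must match dosage columns")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (any(variants$pos < 0)) stop("variant positions must be non-negative")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("non-missing dosages must lie in [0, 2]")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages,
                 subject_ids = rownames(dosages),
                 variants = as.data.frame(variants)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Read genotypes from a dosage TSV or a VCF
#'
#' The dosage layout is a TSV with a `subject_id` column and one numeric
#' column per variant, plus a sidecar variant-metadata TSV. For VCF input
#' the per-genotype dosage is the `DS` FORMAT field when present, else the
#' alt-allele count of `GT`.
#'
#' @param path path to the dosage TSV or VCF.
#' @param format one of `"dosage_tsv"`, `"vcf"`.
#' @param variant_meta path to the sidecar variant-metadata TSV (dosage_tsv
#'   only); defaults to `path` with `_dosages.tsv` replaced by
#'   `_variants.tsv`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf"),
                           variant_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dosage_tsv") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(d)) stop("dosage TSV needs a subject_id column")
    if (is.null(variant_meta))
      variant_meta <- sub("_dosages\\.tsv$", "_variants.tsv", path)
    vm <- utils::read.table(variant_meta, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    dos <- as.matrix(d[, setdiff(names(d), "subject_id"), drop = FALSE])
    if (!is.numeric(dos)) {
      bad <- which(apply(d[, -1, drop = FALSE], 2,
                         function(x) any(is.na(suppressWarnings(as.numeric(x))) & !is.na(x))))
      stop("malformed dosage value in column(s): ",
           paste(names(bad), collapse = ", "))
    }
    rownames(dos) <- d$subject_id
    dos <- dos[, vm$id, drop = FALSE]
    return(new_genotype_matrix(dos, vm))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    dos <- t(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ploidy <- nchar(gsub("[^/|]", "", gt)) + 1L
    ploidy[is.na(gt)] <- NA
    if (length(unique(stats::na.omit(as.vector(ploidy)))) > 1L)
      stop("mixed ploidy in VCF genotypes")
    cnt <- function(x) {
      if (is.na(x)) return(NA_real_)
      sum(strsplit(x, "[/|]")[[1]] == "1")
    }
    dos <- t(apply(gt, c(1, 2), cnt))
  }
  n_var <- nrow(fix)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  alt_freq <- colMeans(dos, na.rm = TRUE) / 2
  variants <- data.frame(
    id = ids,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"],
    maf = pmin(alt_freq, 1 - alt_freq),
    info = 1, missing_rate = colMeans(is.na(dos)),
    stringsAsFactors = FALSE
  )
  new_genotype_matrix(dos, variants)
}

#' Filter variants on MAF, imputation INFO, strand ambiguity and duplicates
#'
#' Retains variants with `maf > maf_min` and `info > info_min` (both strict);
#' strand-ambiguous A/T and C/G variants and later duplicates of the same
#' chrom:pos:allele-set are removed when requested.
#'
#' @param g a `genotype_matrix`.
#' @param maf_min,info_min strict lower bounds on MAF and INFO.
#' @param drop_ambiguous,drop_duplicates logical switches.
#' @return List with the filtered `genotype_matrix` and a `report` of counts
#'   and removed ids per reason.
#' @export
qc_filter <- function(g, maf_min = 0.01, info_min = 0.80,
                      drop_ambiguous = TRUE, drop_duplicates = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  removed <- list(maf = character(0), info = character(0),
                  ambiguous = character(0), duplicate = character(0))
  keep <- rep(TRUE, nrow(v))
  bad <- keep & !(v$maf > maf_min)
  removed$maf <- v$id[bad]; keep <- keep & !bad
  bad <- keep & !(v$info > info_min)
  removed$info <- v$id[bad]; keep <- keep & !bad
  if (drop_ambiguous) {
    pair <- paste(pmin(v$ref_allele, v$alt_allele),
                  pmax(v$ref_allele, v$alt_allele))
    amb <- pair %in% c("A T", "C G")
    bad <- keep & amb
    removed$ambiguous <- v$id[bad]; keep <- keep & !bad
  }
  if (drop_duplicates) {
    key <- paste(v$chrom, v$pos,
                 pmin(v$ref_allele, v$alt_allele),
                 pmax(v$ref_allele, v$alt_allele))
    dup <- duplicated(key)   # keeps the first occurrence in input order
    bad <- keep & dup
    removed$duplicate <- v$id[bad]; keep <- keep & !bad
  }
  report <- list(
    n_input = nrow(v),
    n_removed_maf = length(removed$maf),
    n_removed_info = length(removed$info),
    n_removed_ambiguous = length(removed$ambiguous),
    n_removed_duplicate = length(removed$duplicate),
    n_retained = sum(keep),
    removed_ids = removed
  )
  out <- new_genotype_matrix(g$dosages[, keep, drop = FALSE],
                             v[keep, , drop = FALSE])
  if (report$n_retained == 0L)
    warning("qc_filter removed every variant", call. = FALSE)
  list(genotypes = out, report = report)
}

#' Harmonise an effect table's alleles against a genotype panel
#'
#' Rows whose effect allele equals the panel alt allele are kept unchanged;
#' rows whose effect allele equals the panel ref allele have their effect
#' column negated (one convention applied uniformly, equivalent to
#' reflecting dosages 2 - d); rows whose allele set does not match the panel
#' are dropped and listed in the report.
#'
#' @param g a `genotype_matrix`.
#' @param table summary statistics or weight table with `effect_allele`,
#'   `other_allele` and an effect column (`beta` or `weight`), keyed by `id`
#'   or `variant_id`.
#' @return List with the harmonised `table` and a `report` (counts and
#'   dropped ids).
#' @export
harmonize <- function(g, table) {
  stopifnot(inherits(g, "genotype_matrix"))
  idcol <- if ("variant_id" %in% names(table)) "variant_id" else "id"
  effcol <- if ("weight" %in% names(table)) "weight" else "beta"
  if (!all(c(idcol, effcol, "effect_allele", "other_allele") %in% names(table)))
    stop("table must carry id/variant_id, effect_allele, other_allele and beta/weight")
  v <- g$variants
  m <- match(table[[idcol]], v$id)
  present <- !is.na(m)
  ref <- v$ref_allele[m]; alt <- v$alt_allele[m]
  same <- present & table$effect_allele == alt & table$other_allele == ref
  flip <- present & table$effect_allele == ref & table$other_allele == alt
  drop <- !(same | flip)
  out <- table[!drop, , drop = FALSE]
  fl <- flip[!drop]
  out[[effcol]][fl] <- -out[[effcol]][fl]
  out$effect_allele[fl] <- alt[!drop][fl]
  out$other_allele[fl] <- ref[!drop][fl]
  list(table = out,
       report = list(n_input = nrow(table), n_kept = sum(same),
                     n_flipped = sum(flip), n_dropped = sum(drop),
                     dropped_ids = table[[idcol]][drop]))
}

# Hard-call genotype indicator products shared by PIHAT and IBS distance.
# Returns pairwise counts of IBS0/IBS1/IBS2 and non-missing variant pairs.
ibs_counts <- function(dos) {
  gc <- round(dos)
  gc[gc < 0] <- 0; gc[gc > 2] <- 2
  M <- !is.na(gc)
  g0 <- (gc == 0); g1 <- (gc == 1); g2 <- (gc == 2)
  g0[!M] <- FALSE; g1[!M] <- FALSE; g2[!M] <- FALSE
  s0 <- g0 * 1; s1 <- g1 * 1; s2 <- g2 * 1
  ibs2 <- tcrossprod(s0) + tcrossprod(s1) + tcrossprod(s2)
  ibs0 <- tcrossprod(s0, s2) + tcrossprod(s2, s0)
  nn <- tcrossprod(M * 1)
  list(ibs0 = ibs0, ibs1 = nn - ibs0 - ibs2, ibs2 = ibs2, n = nn, gc = gc)
}

#' Estimate pairwise relatedness (PIHAT) and apply an exclusion threshold
#'
#' Method-of-moments identity-by-descent from pairwise identity-by-state
#' given alt-allele frequencies (PLINK-style expectations, without
#' small-sample corrections); PIHAT = P(IBD=1)/2 + P(IBD=2), clamped to
#' [0, 1]. For each pair with PIHAT strictly above `pihat_max`, the member
#' with higher genotype missingness is excluded (ties: the
#' lexicographically later subject id).
#'
#' @param g a `genotype_matrix` with at least two subjects.
#' @param pihat_max exclusion threshold (strict).
#' @return List with the symmetric `pihat` matrix, an `excluded` data frame
#'   and the number of estimates clamped into [0, 1].
#' @export
estimate_relatedness <- function(g, pihat_max = 0.2) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages)
  if (n < 2L) stop("need at least 2 subjects")
  ic <- ibs_counts(g$dosages)
  p <- colMeans(ic$gc, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all variants monomorphic; allele frequencies uninformative")
  q <- 1 - p
  w <- as.numeric(poly)  # expectations over polymorphic variants only
  e0_ibd0 <- sum(w * 2 * p^2 * q^2)
  e1_ibd0 <- sum(w * (4 * p^3 * q + 4 * p * q^3))
  e2_ibd0 <- sum(w * (p^4 + q^4 + 4 * p^2 * q^2))
  e1_ibd1 <- sum(w * (2 * p^2 * q + 2 * p * q^2))
  e2_ibd1 <- sum(w * (p^3 + q^3 + p^2 * q + p * q^2))
  Vp <- sum(w)
  # restrict observed IBS counts to polymorphic variants
  ic <- ibs_counts(g$dosages[, poly, drop = FALSE])
  frac <- ic$n / Vp   # non-missing fraction per pair, scales expectations
  frac[frac == 0] <- NA
  P0 <- ic$ibs0 / (e0_ibd0 * frac)
  P1 <- (ic$ibs1 - P0 * e1_ibd0 * frac) / (e1_ibd1 * frac)
  P2 <- (ic$ibs2 - P0 * e2_ibd0 * frac - P1 * e2_ibd1 * frac) / (Vp * frac)
  pihat <- P1 / 2 + P2
  n_clamped <- sum(pihat < 0 | pihat > 1, na.rm = TRUE)
  pihat <- pmin(pmax(pihat, 0), 1)
  diag(pihat) <- 1
  dimnames(pihat) <- list(g$subject_ids, g$subject_ids)
  miss <- rowMeans(is.na(g$dosages))
  names(miss) <- g$subject_ids
  excluded <- data.frame(subject_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  retained <- rep(TRUE, n); names(retained) <- g$subject_ids
  pairs <- which(upper.tri(pihat) & pihat > pihat_max, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-pihat[pairs])
    for (r in ord) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!retained[i] || !retained[j]) next
      ids <- g$subject_ids[c(i, j)]
      drop_id <- if (miss[ids[1]] > miss[ids[2]]) ids[1]
      else if (miss[ids[2]] > miss[ids[1]]) ids[2]
      else max(ids)
      retained[drop_id] <- FALSE
      excluded <- rbind(excluded, data.frame(
        subject_id = drop_id,
        reason = sprintf("PIHAT %.3f > %.3f with %s", pihat[i, j], pihat_max,
                         setdiff(ids, drop_id)),
        stringsAsFactors = FALSE))
    }
  }
  list(pihat = pihat, excluded = excluded,
       retained_subjects = g$subject_ids[retained],
       n_clamped = n_clamped)
}

#' Classical multidimensional scaling of identity-by-state distances
#'
#' Torgerson scaling of d = 1 - (IBS proportion over non-missing variant
#' pairs), the PLINK distance convention. Components are ordered by
#' eigenvalue; variance explained is each eigenvalue over the sum of
#' positive eigenvalues.
#'
#' @param g a `genotype_matrix`.
#' @param k number of components (must be < number of subjects).
#' @return List with `components` (subjects x k), `variance_explained`,
#'   and the eigenvalues.
#' @export
mds_components <- function(g, k = 10L) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages)
  k <- check_count(k, "k")
  if (k >= n) stop("k must be smaller than the number of subjects")
  ic <- ibs_counts(g$dosages)
  ibs_prop <- (ic$ibs1 + 2 * ic$ibs2) / (2 * pmax(ic$n, 1))
  d <- 1 - ibs_prop
  diag(d) <- 0
  # degenerate spectra (e.g. identical subjects) are padded below
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  comp <- fit$points
  if (is.null(comp) || length(comp) == 0L)
    comp <- matrix(0, n, 0)
  if (ncol(comp) < k)  # degenerate spectra: pad with zero coordinates
    comp <- cbind(comp, matrix(0, n, k - ncol(comp)))
  rownames(comp) <- g$subject_ids
  colnames(comp) <- paste0("C", seq_len(k))
  pos <- fit$eig[fit$eig > 1e-12]
  ve <- if (length(pos)) pmax(fit$eig[seq_len(k)], 0) / sum(pos) else rep(0, k)
  list(components = comp, variance_explained = ve, eig = fit$eig)
}

#' Assign subjects to reference ancestry clusters in MDS space
#'
#' Nearest-centroid assignment against labelled reference subjects; study
#' subjects whose distance to their nearest centroid exceeds the given
#' quantile of reference within-cluster distances are flagged as outliers.
#'
#' @param components subjects x k MDS coordinates (reference + study rows).
#' @param ref_labels named vector: cluster label per reference subject id.
#' @param target_cluster cluster whose non-members/outliers are excluded.
#' @param dist_quantile quantile of reference distances defining the
#'   outlier radius.
#' @return Data frame with assignment, distance and keep flag per subject.
#' @export
ancestry_assign <- function(components, ref_labels,
                            target_cluster = NULL, dist_quantile = 0.99) {
  stopifnot(!is.null(rownames(components)))
  refs <- intersect(rownames(components), names(ref_labels))
  if (!length(refs)) stop("no reference subjects present in components")
  labs <- ref_labels[refs]
  cent <- do.call(rbind, lapply(split(refs, labs), function(ids)
    colMeans(components[ids, , drop = FALSE])))
  dmat <- t(apply(components, 1, function(x)
    sqrt(colSums((t(cent) - x)^2))))
  if (is.null(dim(dmat))) dmat <- matrix(dmat, ncol = nrow(cent))
  assign <- rownames(cent)[max.col(-dmat)]
  dist_min <- dmat[cbind(seq_len(nrow(dmat)), max.col(-dmat))]
  radius <- vapply(rownames(cent), function(cl) {
    ids <- refs[labs == cl]
    stats::quantile(dist_min[match(ids, rownames(components))], dist_quantile,
                    names = FALSE)
  }, 0)
  keep <- dist_min <= radius[assign]
  if (!is.null(target_cluster)) keep <- keep & assign == target_cluster
  data.frame(subject_id = rownames(components), cluster = assign,
             distance = dist_min, keep = keep,
             is_reference = rownames(components) %in% refs,
             stringsAsFactors = FALSE)
}
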