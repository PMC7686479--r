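# Plain-text readers/writers for every pipeline artifact.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)

#' Write a genotype matrix as dosage + variant-metadata TSVs
#'
#' @param g a `genotype_matrix`.
#' @param prefix output path prefix; writes `<prefix>_dosages.tsv` and
#'   `<prefix>_variants.tsv`.
#' @return The two paths, invisibly.
#' @export
write_genotypes <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  dpath <- paste0(prefix, "_dosages.tsv")
  vpath <- paste0(prefix, "_variants.tsv")
  d <- data.frame(subject_id = g$subject_ids, g$dosages,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(d, dpath)
  write_tsv(g$variants, vpath)
  invisible(c(dosages = dpath, variants = vpath))
}

#' Write a genotype matrix as a minimal VCF with a DS FORMAT field
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$subject_ids), collapse = "\t")), con)
  body <- vapply(seq_len(nrow(v)), function(i) {
    ds <- g$dosages[, i]
    ds_s <- ifelse(is.na(ds), ".", format(ds, trim = TRUE))
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref_allele[i], v$alt_allele[i],
            ".", "PASS", ".", "DS", ds_s), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Write condition-wise activation matrices and the voxel table
#'
#' One `<condition>.tsv` per condition (subject rows) plus `voxels.tsv`
#' and `groups.tsv` in `dir`.
#'
#' @param act an `activation_data`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_activations <- function(act, dir) {
  stopifnot(inherits(act, "activation_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(act$conditions)) {
    d <- data.frame(subject_id = act$subject_ids, act$conditions[[cond]],
                    check.names = FALSE)
    write_tsv(d, file.path(dir, paste0(cond, ".tsv")))
  }
  write_tsv(act$voxel_table, file.path(dir, "voxels.tsv"))
  write_tsv(data.frame(subject_id = act$subject_ids,
                       group = unname(act$group)),
            file.path(dir, "groups.tsv"))
  invisible(dir)
}

#' Read activation data written by [write_activations()]
#'
#' @param dir directory with `<condition>.tsv`, `voxels.tsv`, `groups.tsv`.
#' @return An `activation_data`.
#' @export
read_activations <- function(dir) {
  vox <- read_tsv(file.path(dir, "voxels.tsv"))
  grp <- read_tsv(file.path(dir, "groups.tsv"))
  files <- setdiff(list.files(dir, pattern = "\\.tsv$"),
                   c("voxels.tsv", "groups.tsv"))
  conds <- lapply(files, function(f) {
    d <- read_tsv(file.path(dir, f))
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$subject_id
    m
  })
  names(conds) <- sub("\\.tsv$", "", files)
  new_activation_data(conds, vox, stats::setNames(grp$group, grp$subject_id))
}

#' Serialise a PLS result as a directory of TSVs
#'
#' Writes singular_values.tsv, behavior_saliences.tsv, voxel_saliences.tsv
#' and, when present, bsr.tsv, brainscores.tsv and clusters.tsv.
#'
#' @param fit a `pls_result`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_pls_result <- function(fit, dir) {
  stopifnot(inherits(fit, "pls_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sv <- data.frame(lv = seq_along(fit$singular_values),
                   singular_value = fit$singular_values,
                   pct_crossblock = fit$pct_crossblock)
  if (!is.null(fit$perm_p)) sv$perm_p <- fit$perm_p
  write_tsv(sv, file.path(dir, "singular_values.tsv"))
  write_tsv(data.frame(cell = rownames(fit$behavior_saliences),
                       fit$behavior_saliences, check.names = FALSE),
            file.path(dir, "behavior_saliences.tsv"))
  write_tsv(data.frame(voxel_id = rownames(fit$voxel_saliences),
                       fit$voxel_saliences, check.names = FALSE),
            file.path(dir, "voxel_saliences.tsv"))
  if (!is.null(fit$bsr))
    write_tsv(data.frame(voxel_id = rownames(fit$bsr), fit$bsr,
                         check.names = FALSE),
              file.path(dir, "bsr.tsv"))
  if (!is.null(fit$brainscores))
    write_tsv(data.frame(subject_id = rownames(fit$brainscores),
                         fit$brainscores, check.names = FALSE),
              file.path(dir, "brainscores.tsv"))
  if (!is.null(fit$clusters))
    write_tsv(fit$clusters, file.path(dir, "clusters.tsv"))
  invisible(dir)
}
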