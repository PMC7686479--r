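# Fixture builders shared across test files; everything is generated in
# code so no data files ship with the package.

tiny_config <- function(...) {
  defaults <- list(n_subjects = 60L, n_variants = 100L, ld_block_size = 5L,
                   within_block_r = 0.5, n_genes = 5L, snps_per_gene = 2L,
                   n_voxels = 60L, grid_dims = c(5L, 4L, 3L),
                   signal_fraction = 0.35, noise_sd = 1, seed = 11L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Hand-built genotype panel with full metadata control.
make_geno <- function(dosages, chrom = NULL, pos = NULL,
                      ref = NULL, alt = NULL, maf = NULL, info = NULL) {
  dosages <- as.matrix(dosages)
  V <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep(1L, V)
  if (is.null(pos)) pos <- seq_len(V) * 1000L
  if (is.null(ref)) ref <- rep("A", V)
  if (is.null(alt)) alt <- rep("G", V)
  if (is.null(maf)) {
    f <- colMeans(dosages, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
  }
  if (is.null(info)) info <- rep(1, V)
  ids <- if (!is.null(colnames(dosages))) colnames(dosages)
  else sprintf("v%03d", seq_len(V))
  new_genotype_matrix(dosages, data.frame(
    id = ids, chrom = chrom, pos = pos, ref_allele = ref, alt_allele = alt,
    maf = maf, info = info, missing_rate = colMeans(is.na(dosages)),
    stringsAsFactors = FALSE))
}

# HWE dosages at given alt frequencies, independent variants.
hwe_dosages <- function(n, freqs, seed = 1) {
  withr::with_seed(seed, {
    sapply(freqs, function(p) stats::rbinom(n, 2L, p))
  })
}

# Small activation dataset with an optional planted pattern in one cell.
make_activation <- function(n = 40, V = 24, grid = c(4, 3, 2),
                            conditions = c("emotional_faces", "neutral_faces", "shapes"),
                            seed = 5) {
  withr::with_seed(seed, {
    group <- rep(c("female", "male"), length.out = n)
    conds <- lapply(conditions, function(cc) {
      m <- matrix(stats::rnorm(n * V), n, V)
      rownames(m) <- sprintf("S%04d", seq_len(n))
      colnames(m) <- sprintf("V%05d", seq_len(V))
      m
    })
    names(conds) <- conditions
    coords <- arrayInd(seq_len(V), grid)
    vox <- data.frame(voxel_id = sprintf("V%05d", seq_len(V)),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3])
    new_activation_data(conds, vox,
                        stats::setNames(group, sprintf("S%04d", seq_len(n))))
  })
}

# Brute-force flood fill used as the cluster oracle.
flood_fill_clusters <- function(mask, voxel_table, connectivity = 6L) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[nz == 1, , drop = FALSE],
                "18" = off[nz >= 1 & rowSums(abs(off) > 0) <= 2, , drop = FALSE],
                "26" = off[nz >= 1, , drop = FALSE])
  key <- paste(voxel_table$x, voxel_table$y, voxel_table$z)
  lut <- stats::setNames(seq_along(key), key)
  labels <- rep(NA_integer_, length(mask))
  cur <- 0L
  recurse <- function(v) {
    labels[v] <<- cur
    for (r in seq_len(nrow(off))) {
      k <- paste(voxel_table$x[v] + off[r, 1], voxel_table$y[v] + off[r, 2],
                 voxel_table$z[v] + off[r, 3])
      w <- lut[k]
      if (!is.na(w) && mask[w] && is.na(labels[w])) recurse(w)
    }
  }
  for (v in which(mask)) {
    if (is.na(labels[v])) {
      cur <- cur + 1L
      recurse(v)
    }
  }
  labels
}

# Exhaustive greedy clumping oracle: re-scans all pairs each round.
clump_oracle <- function(ss, dos, r2_max, window_kb, p_index_max = 1) {
  assigned <- rep(NA_character_, nrow(ss))
  names(assigned) <- ss$id
  repeat {
    open <- which(is.na(assigned) & ss$p <= p_index_max)
    if (!length(open)) break
    open <- open[order(ss$p[open], ss$pos[open], ss$id[open])]
    i <- open[1]
    assigned[i] <- ss$id[i]
    for (j in which(is.na(assigned))) {
      if (ss$chrom[j] != ss$chrom[i]) next
      if (abs(ss$pos[j] - ss$pos[i]) > window_kb * 1000) next
      r <- suppressWarnings(stats::cor(dos[, ss$id[i]], dos[, ss$id[j]]))
      if (!is.na(r) && r^2 >= r2_max) assigned[j] <- ss$id[i]
    }
  }
  assigned
}
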