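#' LD reference panels
#'
#' An `ld_panel` stores signed allelic correlations `r` between variants.
#' Correlations are kept block-wise: variants are partitioned into LD blocks,
#' pairs within a block have a stored correlation, pairs across blocks have
#' `r = 0`, and pairs involving a variant absent from the panel have unknown
#' LD (`NA`). This mirrors how reference LD behaves in practice (a reference
#' cohort covers only part of the meta-analysis variants) and keeps panels
#' over 1e5 variants tractable.
#'
#' @param variants A tibble with columns `SNP` and `BLOCK` (and optionally
#'   `CHR`, `BP`).
#' @param blocks A list of symmetric correlation matrices, one per block, with
#'   dimnames equal to the member SNP ids.
#' @return An object of class `ld_panel`.
#' @export
new_ld_panel <- function(variants, blocks) {
  assert_cols(variants, c("SNP", "BLOCK"), "ld_panel variants")
  structure(list(variants = as_tibble(variants), blocks = blocks),
            class = "ld_panel")
}

#' Coerce to an LD panel
#'
#' A plain symmetric correlation matrix with SNP dimnames becomes a
#' single-block panel.
#'
#' @param x An `ld_panel` or a square correlation matrix with dimnames.
#' @return An `ld_panel`.
#' @export
as_ld_panel <- function(x) {
  if (inherits(x, "ld_panel")) return(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort("correlation matrix needs SNP ids as dimnames",
            class = "migwas_schema_error")
    }
    return(new_ld_panel(tibble(SNP = rownames(x), BLOCK = 1L), list(x)))
  }
  abort("cannot coerce to ld_panel", class = "migwas_schema_error")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d variants in %d blocks\n",
              nrow(x$variants), length(x$blocks)))
  invisible(x)
}

#' Simulate a block-structured LD panel
#'
#' Partitions `n_variants` into `n_blocks` contiguous blocks and gives each
#' block an AR(1) correlation structure: variants `k` positions apart within a
#' block have signed correlation `rho^k` with `rho = block_decay`; variants in
#' different blocks are uncorrelated. AR(1) matrices are positive definite for
#' `rho` in `[0, 1)`, so the construction is always a valid correlation
#' structure. Blocks are laid out along 22 autosomes with large inter-block
#' gaps; coordinates are deterministic given the configuration.
#'
#' @param config A [sim_config()].
#' @return An `ld_panel` whose `variants` tibble carries `SNP`, `CHR`, `BP`,
#'   `BLOCK`.
#' @examples
#' panel <- simulate_ld_panel(sim_config(n_variants = 30, n_blocks = 3))
#' ld_matrix(panel, panel$variants$SNP[1:4])
#' @export
simulate_ld_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  rho <- config$block_decay
  block_of <- sort(rep_len(seq_len(config$n_blocks), n))
  sizes <- tabulate(block_of, nbins = config$n_blocks)

  chr <- ((seq_len(config$n_blocks) - 1L) %% 22L) + 1L
  spacing <- 5000L      # bp between adjacent variants within a block
  gap <- 600000L        # bp between consecutive blocks on a chromosome
  bp <- integer(n)
  variant_block_start <- c(1L, head(cumsum(sizes), -1) + 1L)
  for (b in seq_len(config$n_blocks)) {
    prev_on_chr <- which(chr[seq_len(b - 1L)] == chr[b])
    start <- if (length(prev_on_chr) == 0) 1e6 else {
      last <- max(prev_on_chr)
      bp[variant_block_start[last] + sizes[last] - 1L] + gap
    }
    idx <- variant_block_start[b] + seq_len(sizes[b]) - 1L
    bp[idx] <- as.integer(start + (seq_len(sizes[b]) - 1L) * spacing)
  }

  snp <- sprintf("rs%06d", seq_len(n))
  variants <- tibble(SNP = snp, CHR = chr[block_of], BP = bp, BLOCK = block_of)

  # one matrix per distinct block size; AR(1) depends only on size and rho
  proto <- list()
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    m <- sizes[b]
    key <- as.character(m)
    if (is.null(proto[[key]])) proto[[key]] <- rho^abs(outer(1:m, 1:m, "-"))
    mat <- proto[[key]]
    ids <- snp[block_of == b]
    dimnames(mat) <- list(ids, ids)
    blocks[[b]] <- mat
  }
  new_ld_panel(variants, blocks)
}

#' Dense signed-correlation matrix for a set of variants
#'
#' Looks pairs up in the panel: within-block pairs get the stored `r`,
#' cross-block pairs 0, and any pair involving a variant unknown to the panel
#' `NA` (its diagonal entry remains 1).
#'
#' @param panel An `ld_panel` (or coercible matrix).
#' @param snps Character vector of variant ids.
#' @return A symmetric numeric matrix with `snps` as dimnames.
#' @export
ld_matrix <- function(panel, snps) {
  panel <- as_ld_panel(panel)
  k <- length(snps)
  known <- snps %in% panel$variants$SNP
  out <- matrix(NA_real_, k, k, dimnames = list(snps, snps))
  if (any(known)) {
    out[known, known] <- 0
    info <- panel$variants[match(snps[known], panel$variants$SNP), ]
    for (b in unique(info$BLOCK)) {
      ids <- snps[known][info$BLOCK == b]
      out[ids, ids] <- panel$blocks[[b]][ids, ids, drop = FALSE]
    }
  }
  diag(out) <- 1
  out
}

#' Whether each variant has LD information in the panel
#' @param panel An `ld_panel` (or coercible matrix).
#' @param snps Character vector of variant ids.
#' @return Logical vector along `snps`.
#' @export
ld_known <- function(panel, snps) {
  snps %in% as_ld_panel(panel)$variants$SNP
}

#' Write / read an LD panel as plain text
#'
#' The dense signed-correlation matrix goes to a whitespace-delimited file and
#' the variant list (SNP, CHR, BP, BLOCK) to a tab-delimited sidecar. Intended
#' for panels small enough to materialize densely.
#'
#' @param panel An `ld_panel`.
#' @param matrix_file,variants_file Output/input paths.
#' @return `write_ld_panel()` returns `panel` invisibly; `read_ld_panel()`
#'   returns an `ld_panel`.
#' @export
write_ld_panel <- function(panel, matrix_file, variants_file) {
  panel <- as_ld_panel(panel)
  full <- ld_matrix(panel, panel$variants$SNP)
  full[is.na(full)] <- 0
  utils::write.table(full, matrix_file, row.names = FALSE, col.names = FALSE)
  readr::write_tsv(panel$variants, variants_file)
  invisible(panel)
}

#' @rdname write_ld_panel
#' @export
read_ld_panel <- function(matrix_file, variants_file) {
  variants <- readr::read_tsv(variants_file, show_col_types = FALSE)
  m <- as.matrix(utils::read.table(matrix_file))
  dimnames(m) <- list(variants$SNP, variants$SNP)
  if (!"BLOCK" %in% names(variants)) variants$BLOCK <- 1L
  blocks <- lapply(sort(unique(variants$BLOCK)), function(b) {
    ids <- variants$SNP[variants$BLOCK == b]
    m[ids, ids, drop = FALSE]
  })
  new_ld_panel(variants, blocks)
}
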