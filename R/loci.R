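#' Greedy selection of LD-independent index variants
#'
#' Repeatedly takes the remaining genome-wide significant variant with the
#' lowest p-value as an index and removes every remaining variant in LD with
#' it (`r^2 > r2_index`) until none remain. Variants with unknown LD cannot be
#' excluded by the loop; by default each becomes its own (singleton) index
#' candidate. When a secondary panel is supplied, unknown-LD variants that it
#' covers are first checked against the chosen indices: a variant in LD
#' (`r^2 > r2_index`) with an index is absorbed by it — replacing the index
#' when its own p-value is lower (comparison against the index with the
#' largest `r^2`) — and only the rest become singleton indices. P-value ties
#' are broken by chromosome, position, then allele order, so the result does
#' not depend on input row order.
#'
#' @param gws Tibble of genome-wide significant variants (columns
#'   `SNP, CHR, BP, EA, OA` and `P` or `P`-equivalent; uses `P`).
#' @param panel Primary LD panel ([new_ld_panel()] or coercible matrix).
#' @param r2_index Squared-correlation threshold, default 0.1.
#' @param panel2 Optional secondary LD panel for variants the primary panel
#'   does not cover.
#' @return The rows of `gws` that are indices, with columns `INDEX_ORDER`
#'   (selection order; singletons promoted from unknown LD come last) and
#'   `LD_KNOWN`.
#' @export
select_index_variants <- function(gws, panel, r2_index = 0.1, panel2 = NULL) {
  assert_cols(gws, c("SNP", "CHR", "BP", "EA", "OA", "P"), "GWS table")
  gws <- arrange(as_tibble(gws), .data$P, .data$CHR, .data$BP,
                 .data$EA, .data$OA)
  if (nrow(gws) == 0) {
    return(mutate(gws, INDEX_ORDER = integer(0), LD_KNOWN = logical(0)))
  }
  panel <- as_ld_panel(panel)
  known <- ld_known(panel, gws$SNP)

  kn <- gws[known, ]
  R <- ld_matrix(panel, kn$SNP)
  remaining <- seq_len(nrow(kn))
  index_idx <- integer(0)
  while (length(remaining) > 0) {
    pick <- remaining[1]  # rows are p-ordered
    index_idx <- c(index_idx, pick)
    r2 <- R[pick, remaining]^2
    remaining <- remaining[!(r2 > r2_index)]  # drops pick itself (r2 = 1)
  }
  indices <- mutate(kn[index_idx, ],
                    INDEX_ORDER = seq_along(index_idx), LD_KNOWN = TRUE)

  unk <- gws[!known, ]
  if (nrow(unk) > 0 && !is.null(panel2)) {
    panel2 <- as_ld_panel(panel2)
    in2 <- ld_known(panel2, unk$SNP)
    absorbed <- rep(FALSE, nrow(unk))
    for (i in which(in2)) {
      idx_in2 <- ld_known(panel2, indices$SNP)
      if (!any(idx_in2)) next
      r2 <- ld_matrix(panel2, c(unk$SNP[i], indices$SNP[idx_in2]))[1, -1]^2
      hits <- which(!is.na(r2) & r2 > r2_index)
      if (length(hits) == 0) next
      absorbed[i] <- TRUE
      best <- which(idx_in2)[hits[which.max(r2[hits])]]
      if (unk$P[i] < indices$P[best]) {  # replace the index it tags
        repl <- mutate(unk[i, ], INDEX_ORDER = indices$INDEX_ORDER[best],
                       LD_KNOWN = FALSE)
        indices[best, ] <- repl[, names(indices)]
      }
    }
    unk <- unk[!absorbed, ]
  }
  if (nrow(unk) > 0) {
    unk <- mutate(unk, INDEX_ORDER = max(c(0L, indices$INDEX_ORDER)) +
                    row_number(), LD_KNOWN = FALSE)
    indices <- bind_rows(indices, unk)
  }
  arrange(indices, .data$INDEX_ORDER)
}

merge_intervals <- function(loci, merge_gap) {
  # loci: tibble CHR, START, END (1-based inclusive), MEMBERS (list of SNP ids)
  out <- list()
  for (ch in unique(loci$CHR)) {
    sub <- arrange(filter(loci, .data$CHR == ch), .data$START, .data$END)
    cur <- sub[1, ]
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      nxt <- sub[i, ]
      if (nxt$START - cur$END < merge_gap) {
        cur$END <- max(cur$END, nxt$END)
        cur$START <- min(cur$START, nxt$START)
        cur$MEMBERS[[1]] <- union(cur$MEMBERS[[1]], nxt$MEMBERS[[1]])
        cur$INDEX[[1]] <- union(cur$INDEX[[1]], nxt$INDEX[[1]])
      } else {
        out[[length(out) + 1]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1]] <- cur
  }
  bind_rows(out)
}

#' Define risk loci from index variants
#'
#' Three passes reproduce the locus-building algorithm:
#' 1. an LD block around each index variant spans all GWS variants in high LD
#'    with it (`r^2 > r2_block`; an index with no such partner yields a 1-bp
#'    locus at its own position), and blocks on the same chromosome closer
#'    than `merge_gap` (end of one to start of the next) are merged;
#' 2. every remaining GWS variant joins its nearest locus on its chromosome
#'    (distance to the closest locus boundary, 0 inside; ties go to the
#'    lower-coordinate locus) and locus boundaries are updated;
#' 3. loci within `merge_gap` of each other are merged again.
#' Final loci on one chromosome are therefore separated by at least
#' `merge_gap`, and every GWS variant belongs to exactly one locus.
#'
#' @param indices Output of [select_index_variants()] (or a subset of `gws`
#'   rows).
#' @param gws The full GWS table the indices were selected from.
#' @param panel LD panel.
#' @param r2_block High-LD threshold for block spanning, default 0.6.
#' @param merge_gap Merge distance in bp, default 250,000.
#' @return A `migwas_loci` tibble: `LOCUS, CHR, START, END, N_MEMBERS,
#'   LEAD_SNP, LEAD_P, INDEX` (list of index SNPs), `MEMBERS` (list of member
#'   SNPs).
#' @export
define_loci <- function(indices, gws, panel, r2_block = 0.6,
                        merge_gap = 250000) {
  assert_cols(gws, c("SNP", "CHR", "BP", "EA", "OA", "P"), "GWS table")
  if (!all(indices$SNP %in% gws$SNP)) {
    abort("index variant not present in the GWS table",
          class = "migwas_data_error")
  }
  gws <- arrange(as_tibble(gws), .data$CHR, .data$BP)
  panel <- as_ld_panel(panel)

  # pass 1: block spanning
  blocks <- vector("list", nrow(indices))
  for (i in seq_len(nrow(indices))) {
    ix <- indices$SNP[i]
    chr <- indices$CHR[i]
    same_chr <- gws[gws$CHR == chr, ]
    r <- ld_matrix(panel, unique(c(ix, same_chr$SNP)))[ix, same_chr$SNP]
    mem <- same_chr$SNP[!is.na(r) & r^2 > r2_block]
    mem <- union(mem, ix)
    bp <- gws$BP[match(mem, gws$SNP)]
    blocks[[i]] <- tibble(CHR = chr, START = min(bp), END = max(bp),
                          MEMBERS = list(mem), INDEX = list(ix))
  }
  loci <- merge_intervals(bind_rows(blocks), merge_gap)

  # pass 2: nearest-locus assignment of leftover GWS variants
  assigned <- unique(unlist(loci$MEMBERS))
  left <- gws[!(gws$SNP %in% assigned), ]
  for (i in seq_len(nrow(left))) {
    cand <- which(loci$CHR == left$CHR[i])
    if (length(cand) == 0) {  # defensive: isolated chromosome
      loci <- bind_rows(loci, tibble(CHR = left$CHR[i], START = left$BP[i],
                                     END = left$BP[i],
                                     MEMBERS = list(left$SNP[i]),
                                     INDEX = list(character(0))))
      next
    }
    d <- pmax(0, loci$START[cand] - left$BP[i], left$BP[i] - loci$END[cand])
    best <- cand[order(d, loci$START[cand])][1]
    loci$MEMBERS[[best]] <- union(loci$MEMBERS[[best]], left$SNP[i])
    loci$START[best] <- min(loci$START[best], left$BP[i])
    loci$END[best] <- max(loci$END[best], left$BP[i])
  }

  # pass 3: final merge
  loci <- merge_intervals(loci, merge_gap)

  # membership by final interval, lead = minimum p (ties: bp, alleles)
  loci <- arrange(loci, .data$CHR, .data$START)
  loci$MEMBERS <- lapply(seq_len(nrow(loci)), function(i) {
    gws$SNP[gws$CHR == loci$CHR[i] & gws$BP >= loci$START[i] &
              gws$BP <= loci$END[i]]
  })
  lead <- map_chr(loci$MEMBERS, function(mem) {
    sub <- arrange(gws[match(mem, gws$SNP), ], .data$P, .data$BP,
                   .data$EA, .data$OA)
    sub$SNP[1]
  })
  out <- mutate(loci,
                LOCUS = row_number(),
                N_MEMBERS = lengths(.data$MEMBERS),
                LEAD_SNP = lead,
                LEAD_P = gws$P[match(lead, gws$SNP)]) %>%
    select("LOCUS", "CHR", "START", "END", "N_MEMBERS", "LEAD_SNP", "LEAD_P",
           "INDEX", "MEMBERS")
  class(out) <- c("migwas_loci", class(out))
  out
}

#' One-call risk-locus pipeline
#'
#' Filters a meta-analysis table to genome-wide significance, selects index
#' variants, builds loci and (when gene annotation is given) names them.
#'
#' @param meta Meta-analysis tibble from [ivw_meta()] (or any table with
#'   `SNP, CHR, BP, EA, OA, P`).
#' @param panel LD panel.
#' @param genes Optional gene annotation tibble (see [read_gene_bed()]).
#' @param gws_p Significance threshold, default 5e-8.
#' @param r2_index,r2_block,merge_gap,panel2,window Passed through to the
#'   underlying steps.
#' @return A `migwas_loci` tibble (named when `genes` is supplied).
#' @export
risk_loci <- function(meta, panel, genes = NULL, gws_p = GWS_P,
                      r2_index = 0.1, r2_block = 0.6, merge_gap = 250000,
                      panel2 = NULL, window = 250000) {
  gws <- filter(as_tibble(meta), .data$P < gws_p)
  idx <- select_index_variants(gws, panel, r2_index, panel2)
  loci <- define_loci(idx, gws, panel, r2_block, merge_gap)
  if (!is.null(genes)) loci <- name_loci(loci, gws, genes, window)
  loci
}

#' Name loci by their lead variant's nearest gene
#'
#' Each locus is named after the protein-coding gene nearest to its lead
#' variant, or after the nearest noncoding gene when no protein-coding gene
#' lies within `window` bp. The prefix `"Near "` is added when the lead
#' variant does not overlap any gene transcript. With no protein-coding gene
#' in the window and no noncoding gene on record, the name falls back to
#' `"chr:pos"`.
#'
#' @param loci A `migwas_loci` tibble from [define_loci()].
#' @param gws The GWS table (for lead-variant positions).
#' @param genes Gene tibble with `CHR, START, END, NAME, PROTEIN_CODING`
#'   (1-based inclusive; see [read_gene_bed()]).
#' @param window Search window for protein-coding genes, bp.
#' @return `loci` with `NAME` and `IS_NEAR` columns added.
#' @export
name_loci <- function(loci, gws, genes, window = 250000) {
  assert_cols(genes, c("CHR", "START", "END", "NAME", "PROTEIN_CODING"),
              "gene table")
  lead_bp <- gws$BP[match(loci$LEAD_SNP, gws$SNP)]
  nm <- character(nrow(loci)); near <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    g <- filter(as_tibble(genes), .data$CHR == loci$CHR[i])
    if (nrow(g) > 0) {
      d <- pmax(0, g$START - lead_bp[i], lead_bp[i] - g$END)
    } else d <- numeric(0)
    near[i] <- !any(d == 0)
    pc <- which(g$PROTEIN_CODING & d <= window)
    nc <- which(!g$PROTEIN_CODING)
    pick <- NA_integer_
    if (length(pc) > 0) {
      pick <- pc[order(d[pc], g$START[pc], g$NAME[pc])][1]
    } else if (length(nc) > 0) {
      pick <- nc[order(d[nc], g$START[nc], g$NAME[nc])][1]
    }
    if (is.na(pick)) {
      nm[i] <- sprintf("%s:%d", loci$CHR[i], lead_bp[i])
      near[i] <- TRUE
      inform(sprintf("locus %d: no gene within %d bp; named by position",
                     loci$LOCUS[i], window))
    } else {
      nm[i] <- if (near[i]) paste("Near", g$NAME[pick]) else g$NAME[pick]
    }
  }
  mutate(loci, NAME = nm, IS_NEAR = near)
}

#' Read gene annotation from BED
#'
#' Expects BED columns chrom, chromStart (0-based), chromEnd (half-open),
#' name, score (ignored), strand (ignored), plus a final biotype column
#' (`protein_coding` marks coding genes). Converts to 1-based inclusive
#' coordinates.
#'
#' @param file Path to a tab-delimited BED file without header.
#' @return Tibble with `CHR, START, END, NAME, BIOTYPE, PROTEIN_CODING`.
#' @export
read_gene_bed <- function(file) {
  raw <- readr::read_tsv(file, col_names = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 4) {
    abort("BED gene annotation needs at least chrom, start, end, name",
          class = "migwas_schema_error")
  }
  biotype <- if (ncol(raw) >= 7) raw[[7]] else
    if (ncol(raw) >= 5 && !is.numeric(raw[[5]])) raw[[5]] else "protein_coding"
  tibble(CHR = gsub("^chr", "", as.character(raw[[1]])),
         START = raw[[2]] + 1L, END = raw[[3]], NAME = raw[[4]],
         BIOTYPE = biotype,
         PROTEIN_CODING = biotype == "protein_coding")
}

#' Write loci to disk
#'
#' A tab-delimited locus table (`CHR, START, END, N_MEMBERS, LEAD_SNP,
#' LEAD_P, NAME`) plus a JSON membership map.
#'
#' @param loci A `migwas_loci` tibble.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>_members.json`.
#' @return `prefix`, invisibly.
#' @export
write_loci <- function(loci, prefix) {
  flat <- select(as_tibble(loci), -dplyr::any_of(c("INDEX", "MEMBERS")))
  readr::write_tsv(flat, paste0(prefix, ".tsv"))
  members <- setNames(loci$MEMBERS, paste0("locus_", loci$LOCUS))
  jsonlite::write_json(members, paste0(prefix, "_members.json"))
  invisible(prefix)
}
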