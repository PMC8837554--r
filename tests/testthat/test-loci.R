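test_that("greedy index selection follows the p-ordered exclusion loop", {
  # single variant is its own index
  g1 <- mk_gws(100, 1e-9)
  expect_equal(select_index_variants(g1, mk_ld(g1$SNP))$SNP, g1$SNP)

  # all mutually correlated above threshold: only the minimum-p survives
  g <- mk_gws(c(100, 200, 300), c(1e-9, 1e-12, 1e-10))
  R <- mk_ld(g$SNP, list(c(1, 2, 0.6), c(1, 3, 0.6), c(2, 3, 0.6)))
  expect_equal(select_index_variants(g, R)$SNP, "s02")

  # hand-executed loop: p = (1e-12, 1e-10, 1e-9, 1e-8),
  # r2(1,2) = 0.5, r2(1,3) = 0.05, r2(3,4) = 0.3 -> indices {1, 3}
  g4 <- mk_gws(c(100, 200, 300, 400), c(1e-12, 1e-10, 1e-9, 1e-8))
  R4 <- mk_ld(g4$SNP, list(c(1, 2, sqrt(0.5)), c(1, 3, sqrt(0.05)),
                           c(3, 4, sqrt(0.3))))
  idx <- select_index_variants(g4, R4)
  expect_equal(idx$SNP, c("s01", "s03"))
  expect_equal(idx$INDEX_ORDER, 1:2)

  # empty input is an empty result, not an error
  expect_equal(nrow(select_index_variants(g4[0, ], R4)), 0L)
})

test_that("index selection is invariant to row order and honours unknown LD", {
  g <- mk_gws(c(100, 200, 300, 400, 500),
              c(1e-12, 1e-10, 1e-9, 1e-8, 1e-8))
  R <- mk_ld(g$SNP[1:3], list(c(1, 2, 0.8)))  # s04, s05 unknown to the panel
  idx <- select_index_variants(g, R)
  expect_setequal(idx$SNP, c("s01", "s03", "s04", "s05"))
  expect_false(any(idx$LD_KNOWN[idx$SNP %in% c("s04", "s05")]))

  withr::with_seed(21, {
    for (i in 1:10) {
      shuffled <- g[sample(nrow(g)), ]
      expect_equal(select_index_variants(shuffled, R)$SNP, idx$SNP)
    }
  })
})

test_that("a secondary panel absorbs unknown-LD variants and can replace an index", {
  g <- mk_gws(c(100, 200, 300), c(1e-10, 1e-12, 1e-9))
  R1 <- mk_ld(g$SNP[1])                      # only s01 known to panel 1
  R2 <- mk_ld(g$SNP, list(c(1, 2, 0.9)))     # panel 2 links s02 to s01

  # s02 (lower p) is in LD with index s01 and replaces it; s03 stays singleton
  idx <- select_index_variants(g, R1, panel2 = R2)
  expect_setequal(idx$SNP, c("s02", "s03"))

  # if the unknown variant has the higher p it is absorbed without replacing
  g_hi <- dplyr::mutate(g, P = c(1e-12, 1e-10, 1e-9))
  idx2 <- select_index_variants(g_hi, R1, panel2 = R2)
  expect_setequal(idx2$SNP, c("s01", "s03"))
})

test_that("locus building spans blocks, merges, assigns and names per the rules", {
  # blocks [100k, 200k] and [400k, 500k]: 200 kb gap < 250 kb, merged
  g <- mk_gws(c(100e3, 200e3, 400e3, 500e3), c(1e-12, 1e-9, 1e-11, 1e-9))
  R <- mk_ld(g$SNP, list(c(1, 2, 0.9), c(3, 4, 0.9)))
  idx <- select_index_variants(g, R)
  loci <- define_loci(idx, g, R)
  expect_equal(nrow(loci), 1L)
  expect_equal(c(loci$START, loci$END), c(100e3, 500e3))
  expect_equal(loci$LEAD_SNP, "s01")
  expect_equal(loci$N_MEMBERS, 4L)

  # gap 260 kb stays two loci after pass 1, but a stray GWS variant at 330 kb
  # (nearer the first locus) extends it; the new 130 kb gap merges in pass 3
  g2 <- mk_gws(c(100e3, 200e3, 330e3, 460e3, 500e3),
               c(1e-12, 1e-9, 1e-8 / 2, 1e-11, 1e-9))
  R2 <- mk_ld(g2$SNP, list(c(1, 2, 0.9), c(4, 5, 0.9)))
  idx2 <- select_index_variants(g2, R2)
  expect_setequal(idx2$SNP, c("s01", "s03", "s04"))
  # note: s03 is its own index (r2 unknown to none, uncorrelated) so it forms
  # a 1-bp block; pass-1 merge already joins everything within 250 kb
  loci2 <- define_loci(idx2, g2, R2)
  expect_equal(nrow(loci2), 1L)
  expect_equal(c(loci2$START, loci2$END), c(100e3, 500e3))

  # the same situation with s03 truly unassigned in pass 1: make it excluded
  # by s01 during clumping (r2 > 0.1) but below block LD (r2 < 0.6)
  R3 <- mk_ld(g2$SNP, list(c(1, 2, 0.9), c(1, 3, 0.4), c(4, 5, 0.9)))
  idx3 <- select_index_variants(g2, R3)
  expect_setequal(idx3$SNP, c("s01", "s04"))
  loci3 <- define_loci(idx3, g2, R3)
  expect_equal(nrow(loci3), 1L)   # pass 2 extends to 330 kb, pass 3 merges
  expect_equal(c(loci3$START, loci3$END), c(100e3, 500e3))

  # an index with no high-LD partner yields a 1-bp locus
  g_solo <- mk_gws(c(100e3, 10e6), c(1e-9, 1e-10))
  R_solo <- mk_ld(g_solo$SNP)
  loci_solo <- define_loci(select_index_variants(g_solo, R_solo),
                           g_solo, R_solo)
  expect_equal(loci_solo$END - loci_solo$START, c(0, 0))

  # merging never crosses chromosomes
  g_chr <- dplyr::mutate(mk_gws(c(100e3, 150e3), c(1e-9, 1e-10)),
                         CHR = c(1L, 2L))
  loci_chr <- define_loci(select_index_variants(g_chr, mk_ld(g_chr$SNP)),
                          g_chr, mk_ld(g_chr$SNP))
  expect_equal(nrow(loci_chr), 2L)

  expect_error(define_loci(mk_gws(1, 1e-9, snp = "zz"), g, R),
               class = "migwas_data_error")
})

test_that("locus naming uses nearest genes with the Near prefix", {
  g <- mk_gws(c(100e3, 500e3, 900e3), c(1e-12, 1e-11, 1e-10))
  R <- mk_ld(g$SNP)
  loci <- define_loci(select_index_variants(g, R), g, R)
  genes <- tibble::tibble(
    CHR = 1L,
    START = c(90e3, 510e3, 1250e3, 940e3),
    END = c(120e3, 520e3, 1300e3, 950e3),
    NAME = c("PCG1", "PCG2", "PCG3", "NCG1"),
    PROTEIN_CODING = c(TRUE, TRUE, TRUE, FALSE))
  named <- name_loci(loci, g, genes)
  # lead inside PCG1: bare name
  expect_equal(named$NAME[1], "PCG1")
  expect_false(named$IS_NEAR[1])
  # lead 10 kb from PCG2, overlapping nothing: "Near PCG2"
  expect_equal(named$NAME[2], "Near PCG2")
  expect_true(named$IS_NEAR[2])
  # nearest protein-coding gene 350 kb away but noncoding NCG1 at 40 kb
  expect_equal(named$NAME[3], "Near NCG1")

  # no gene at all on the chromosome: positional fallback
  genes_other <- dplyr::mutate(genes, CHR = 9L)
  named_fb <- suppressMessages(name_loci(loci, g, genes_other))
  expect_equal(named_fb$NAME, sprintf("1:%d", c(100000L, 500000L, 900000L)))
})

test_that("random locus instances satisfy the algorithm's invariants", {
  withr::with_seed(19, {
    for (rep in 1:60) {
      n <- sample(5:30, 1)
      cfg <- sim_config(n_variants = n, n_blocks = sample(1:4, 1),
                        block_decay = runif(1, 0, 0.95), seed = rep)
      panel <- simulate_ld_panel(cfg)
      gws <- dplyr::mutate(panel$variants, EA = "A", OA = "G",
                           P = 10^runif(n, -12, log10(5e-8)))
      # hide some variants from the panel to exercise unknown-LD promotion
      if (n > 6 && runif(1) < 0.5) {
        keep <- sort(sample(n, n - 2))
        panel <- new_ld_panel(panel$variants[keep, ],
                              panel$blocks)
      }
      idx <- select_index_variants(gws, panel)
      loci <- define_loci(idx, gws, panel)

      # indices pairwise r2 < 0.1 where LD is known
      Ri <- ld_matrix(panel, idx$SNP)
      off <- Ri[upper.tri(Ri)]
      expect_true(all(is.na(off) | off^2 < 0.1 + 1e-12))

      # every GWS variant in exactly one locus
      hits <- vapply(seq_len(nrow(gws)), function(i)
        sum(gws$CHR[i] == loci$CHR & gws$BP[i] >= loci$START &
              gws$BP[i] <= loci$END), integer(1))
      expect_true(all(hits == 1))
      expect_equal(sum(loci$N_MEMBERS), nrow(gws))

      # final loci on one chromosome separated by >= 250 kb (brute force)
      for (ch in unique(loci$CHR)) {
        sub <- dplyr::arrange(loci[loci$CHR == ch, ], START)
        if (nrow(sub) > 1) {
          gaps <- sub$START[-1] - sub$END[-nrow(sub)]
          expect_true(all(gaps >= 250000))
        }
      }

      # fixed point: building loci from the loci's own lead set changes nothing
      expect_true(all(loci$LEAD_P ==
                        vapply(loci$MEMBERS, function(m)
                          min(gws$P[gws$SNP %in% m]), numeric(1))))
    }
  })
})
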