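mk_copies <- function(start, end, contig = "chr1") {
  data.frame(copy_id = paste0("c", seq_along(start)), contig = contig,
             start = start, end = end, stringsAsFactors = FALSE)
}

test_that("genic_overlap boundary arithmetic is half-open with flanks", {
  genes <- gene_features("chr1", 10000, 20000, "+", "gene", "g1")
  # copy 4999..5001 shares exactly one base with the 5000-extended gene
  ctx <- genic_overlap(mk_copies(4999, 5001), genes, flank_bp = 5000)
  expect_equal(ctx$n_genic, 1L)
  expect_equal(ctx$n_flank_only, 1L)
  # one base short: not genic
  ctx2 <- genic_overlap(mk_copies(4998, 5000), genes, flank_bp = 5000)
  expect_equal(ctx2$n_genic, 0L)
  # downstream flank: genic, flank-only
  ctx3 <- genic_overlap(mk_copies(24999, 25100), genes, flank_bp = 5000)
  expect_equal(ctx3$n_genic, 1L)
  expect_equal(ctx3$n_flank_only, 1L)
  # inside the gene body
  ctx4 <- genic_overlap(mk_copies(15000, 15100), genes, flank_bp = 5000)
  expect_equal(ctx4$n_gene_body, 1L)
  expect_equal(ctx4$n_flank_only, 0L)
  # unknown contig: non-genic with a warning
  expect_warning(
    ctx5 <- genic_overlap(mk_copies(15000, 15100, contig = "chrX"), genes),
    "without annotation")
  expect_equal(ctx5$n_genic, 0L)
})

test_that("percent_genic matches simulator truth exactly", {
  sim <- small_burst(seed = 19, n_full = 60, n_der = 60, genome_length = 4e5)
  copies <- data.frame(copy_id = sim$truth$copy_id,
                       contig = sim$truth$contig,
                       start = sim$truth$start, end = sim$truth$end,
                       stringsAsFactors = FALSE)
  ctx <- genic_overlap(copies, sim$genes, flank_bp = 5000)
  expect_equal(ctx$percent_genic, 100 * mean(sim$truth$in_genic))
  expect_equal(ctx$per_copy$genic, unname(sim$truth$in_genic))
})

test_that("independence_test matches the hand chi-square formula", {
  expect_equal(independence_test(rbind(c(10, 10), c(10, 10)))$chi2, 0)
  expect_equal(independence_test(rbind(c(10, 10), c(10, 10)))$p, 1)

  r <- independence_test(rbind(c(30, 70), c(50, 50)))
  expect_equal(r$chi2, 8.3333, tolerance = 1e-4)
  expect_equal(r$chi2, chisq_hand(rbind(c(30, 70), c(50, 50))))
  expect_equal(r$df, 1)

  expect_error(independence_test(rbind(c(0, 0), c(10, 10))), "zero row sum")
  expect_error(independence_test(matrix(c(5, 5), 1)), "2 species")

  # oracle equivalence across small 2x2 tables with positive margins
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    tab <- rbind(c(a, b), c(cc, d))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(independence_test(tab)$chi2, chisq_hand(tab),
                 tolerance = 1e-12)
  }
})

test_that("chi-square type-I error is calibrated for equal proportions", {
  set.seed(51)
  reject <- vapply(1:200, function(i) {
    g1 <- stats::rbinom(1, 200, 0.4)
    g2 <- stats::rbinom(1, 200, 0.4)
    tab <- rbind(c(g1, 200 - g1), c(g2, 200 - g2))
    if (any(colSums(tab) == 0)) return(FALSE)
    independence_test(tab)$p < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(reject) - 0.05), 3 * se)
})

test_that("posthoc_pairwise: correction count, monotonicity, power", {
  tab <- rbind(a = c(40, 60), b = c(40, 60), c = c(40, 60),
               d = c(40, 60), e = c(40, 60), f = c(40, 60))
  pw <- posthoc_pairwise(tab)
  expect_equal(nrow(pw), 15L)                 # k = 6 -> 15 comparisons
  expect_false(any(pw$significant))           # identical rows
  expect_true(all(pw$p_bonferroni >= pw$p_raw))

  # one species at 25% genic vs five at 41%, n = 500 each
  tab2 <- rbind(low = c(125, 375),
                matrix(rep(c(205, 295), 5), ncol = 2, byrow = TRUE,
                       dimnames = list(paste0("s", 1:5), NULL)))
  pw2 <- posthoc_pairwise(tab2, alpha = 0.01)
  vs_low <- pw2$species_i == "low" | pw2$species_j == "low"
  expect_true(all(pw2$significant[vs_low]))
  expect_false(any(pw2$significant[!vs_low]))

  # significant set shrinks (or stays) as alpha decreases
  pw_strict <- posthoc_pairwise(tab2, alpha = 1e-6)
  expect_true(all(pw_strict$significant <= pw2$significant))

  expect_error(posthoc_pairwise(tab[1:2, ]), "at least 3")
})

test_that("transcript_context classifies by sub-feature with CDS priority", {
  feats <- gene_features(
    contig = "chr1",
    start = c(1000, 1000, 1000, 1500, 4500),
    end = c(5000, 5000, 1500, 4500, 5000),
    strand = "+",
    feature_kind = c("gene", "mRNA", "five_prime_UTR", "CDS",
                     "three_prime_UTR"),
    id = c("g1", "t1", "u5", "cds", "u3"),
    parent_id = c(NA, "g1", "t1", "t1", "t1"))

  # squarely inside the CDS
  r <- transcript_context(mk_copies(2000, 2100), feats)
  expect_equal(unname(r$counts["CDS"]), 1L)
  # spanning the 5'UTR/CDS junction: CDS wins by priority
  r2 <- transcript_context(mk_copies(1400, 1600), feats)
  expect_equal(unname(r2$counts["CDS"]), 1L)
  expect_equal(unname(r2$counts["five_prime_UTR"]), 0L)
  # in the 3' UTR only
  r3 <- transcript_context(mk_copies(4600, 4700), feats)
  expect_equal(unname(r3$counts["three_prime_UTR"]), 1L)
  # outside any mRNA
  r4 <- transcript_context(mk_copies(9000, 9100), feats)
  expect_equal(sum(r4$counts), 0L)
})

test_that("planted simulator insertions are classified as annotated", {
  sim <- small_burst(seed = 20, n_full = 40, n_der = 40, genome_length = 3e5)
  copies <- mk_copies(sim$truth$start, sim$truth$end)
  r <- transcript_context(copies, sim$genes)
  mrna <- sim$genes[sim$genes$feature_kind == "mRNA", ]
  in_mrna <- vapply(seq_len(nrow(copies)), function(i) {
    any(mrna$start < copies$end[i] & mrna$end > copies$start[i])
  }, logical(1))
  expect_equal(sum(r$counts[c("five_prime_UTR", "CDS", "three_prime_UTR",
                              "other")]),
               sum(in_mrna))
  expect_equal(!is.na(r$classification$mrna_context), in_mrna)
})
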