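test_that("make_master builds perfect TIRs and a tiling segment map", {
  m <- make_master(865, 24, c(300, 561), seed = 1)
  expect_equal(nchar(m$sequence), 865)
  expect_equal(substr(m$sequence, 1, 24),
               revcomp(substr(m$sequence, 842, 865)))
  seg <- m$segment_map
  expect_equal(seg$start[1], 0L)
  expect_equal(seg$end[nrow(seg)], 865L)
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))  # tiles, no overlap

  # no TIR constraint when tir_length = 0
  m0 <- make_master(100, 0, NULL, seed = 2)
  expect_equal(m0$tir_length, 0L)

  expect_error(make_master(865, 24, c(0, 10)), "strictly inside")
  expect_error(make_master(40, 24, NULL), "infeasible")
  expect_error(make_master(865, 24, c(290, 850)), "strictly inside")
})

test_that("mutate_jc: identity at age 0, closed-form rate, binomial sampling", {
  m <- make_master(seed = 3)
  r0 <- mutate_jc(m$sequence, 2.2e-9, 0)
  expect_identical(r0$sequence, m$sequence)
  expect_equal(r0$substitutions, 0L)

  # p = (3/4)(1 - exp(-(4/3) * 0.12)) = 0.1108922 (closed form)
  expect_equal(jc_expected_p(0.12), 0.1108922, tolerance = 1e-6)

  # binomial sampling oracle: 10,000 sites, 50 replicate seeds
  set.seed(99)
  long <- rnd_dna(10000)
  p_hat <- vapply(1:50, function(i) {
    mutate_jc(long, 1, 0.12)$substitutions / 10000
  }, numeric(1))
  p <- jc_expected_p(0.12)
  se <- sqrt(p * (1 - p) / (10000 * 50))
  expect_lt(abs(mean(p_hat) - p), 3 * se)
})

test_that("simulate_burst degenerate and error cases", {
  m <- make_master(seed = 1)
  sim0 <- simulate_burst(m, burst_model(n_copies = c(full = 0,
                                                     deletion_derivative = 0),
                                        seed = 1),
                         genome_length = 1e4)
  expect_equal(nrow(sim0$truth), 0L)
  expect_equal(nrow(sim0$hits), 0L)
  expect_equal(nchar(sim0$genome[[1]]), 1e4)

  expect_error(
    simulate_burst(m, burst_model(n_copies = c(full = 100,
                                               deletion_derivative = 0),
                                  seed = 1),
                   genome_length = 1e3),
    "genome_length")
})

test_that("every insertion carries a TA target-site duplication", {
  sim <- small_burst(seed = 5, n_full = 20, n_der = 20, genome_length = 1e5)
  g <- sim$genome[[1]]
  for (i in seq_len(nrow(sim$truth))) {
    s <- sim$truth$start[i]; e <- sim$truth$end[i]
    expect_equal(substr(g, s - 1, s), "TA")
    expect_equal(substr(g, e + 1, e + 2), "TA")
  }
})

test_that("length conservation: genome = background + copies + TSDs", {
  sim <- small_burst(seed = 6, n_full = 15, n_der = 25, genome_length = 2e5)
  copy_len <- sum(sim$truth$end - sim$truth$start)
  expect_equal(nchar(sim$genome[[1]]),
               2e5 + copy_len + 4L * nrow(sim$truth))
})

test_that("truth, MSA and genome are mutually consistent", {
  sim <- small_burst(seed = 7, n_full = 15, n_der = 15, genome_length = 1e5)
  g <- sim$genome[[1]]
  master_row <- sim$master$sequence
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$msa[[sim$truth$copy_id[i]]]
    # realized substitutions / aligned length == p-distance to master
    p <- p_distance(row, master_row)
    aligned_len <- sum(strsplit(row, "")[[1]] != "-")
    expect_equal(p, sim$truth$realized_substitutions[i] / aligned_len)
    # genome substring is the (strand-adjusted) copy sequence
    ins <- substr(g, sim$truth$start[i] + 1, sim$truth$end[i])
    if (sim$truth$strand[i] == "-") ins <- revcomp(ins)
    expect_identical(ins, gsub("-", "", row))
  }
})

test_that("identical seeds give identical simulations", {
  a <- small_burst(seed = 8, n_full = 10, n_der = 10, genome_length = 1e5)
  b <- small_burst(seed = 8, n_full = 10, n_der = 10, genome_length = 1e5)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_identical(a$hits, b$hits)
  expect_identical(a$msa, b$msa)

  c <- small_burst(seed = 9, n_full = 10, n_der = 10, genome_length = 1e5)
  expect_false(identical(a$genome, c$genome))
})

test_that("mean copy-to-master p matches the Jukes-Cantor forward map", {
  # rate * age fixed at 0.20 (age_sd = 0): expected p = 0.1755537
  sim <- small_burst(seed = 10, n_full = 200, n_der = 200,
                     genome_length = 6e5, rate_s = 2.2e-9,
                     age_mean = 0.20 / 2.2e-9, age_sd = 0)
  p_exp <- jc_expected_p(0.20)
  expect_equal(p_exp, 0.1755537, tolerance = 1e-6)
  p_obs <- vapply(seq_len(nrow(sim$truth)), function(i) {
    sim$truth$realized_substitutions[i] /
      (nchar(gsub("-", "", sim$msa[[i]])))
  }, numeric(1))
  se <- sqrt(p_exp * (1 - p_exp) / (865 * 400))  # conservative: full length
  expect_lt(abs(mean(p_obs) - p_exp), 3 * se)
})

test_that("write_burst emits a complete, re-readable artefact set", {
  sim <- small_burst(seed = 11, n_full = 6, n_der = 6, genome_length = 8e4)
  d <- withr::local_tempdir()
  write_burst(sim, d)
  expect_setequal(list.files(d),
                  c("genome.fasta", "master.fasta", "truth.bed", "truth.tsv",
                    "hits.blast.tsv", "hits.rm.out", "copies.aln.fasta",
                    "genes.gff3"))
  expect_equal(read_fasta(file.path(d, "genome.fasta"))[[1]],
               sim$genome[[1]])
  expect_equal(nrow(read_blast_tab(file.path(d, "hits.blast.tsv"))),
               nrow(sim$hits))
  expect_equal(nrow(read_repeatmasker_out(file.path(d, "hits.rm.out"))),
               nrow(sim$hits))
  genes <- read_gene_annotation(file.path(d, "genes.gff3"), "gff3")
  expect_equal(nrow(genes), nrow(sim$genes))
})
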