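test_that("local_align scores canonical cases", {
  a <- local_align(strrep("ACGT", 5), strrep("ACGT", 5))
  expect_equal(a$score, 40)
  expect_equal(a$query_interval, c(0, 20))
  expect_equal(a$subject_interval, c(0, 20))
  expect_equal(a$p_distance, 0)

  # best between ACGT and TTTT is a single matching T
  b <- local_align("ACGT", "TTTT")
  expect_equal(b$score, 2)
  expect_equal(b$query_aln, "T")
})

test_that("local_align agrees with the plain-R DP oracle on random pairs", {
  set.seed(61)
  for (rep in 1:120) {
    q <- rnd_dna(sample(1:8, 1))
    s <- rnd_dna(sample(1:8, 1))
    expect_equal(local_align(q, s)$score, sw_oracle_score(q, s),
                 info = paste(q, s))
  }
})

test_that("local_align score is symmetric in its arguments", {
  set.seed(62)
  for (rep in 1:20) {
    q <- rnd_dna(sample(5:60, 1))
    s <- rnd_dna(sample(5:60, 1))
    expect_equal(local_align(q, s)$score, local_align(s, q)$score)
  }
})

test_that("alignment output is self-consistent", {
  set.seed(63)
  for (rep in 1:10) {
    q <- rnd_dna(80); s <- rnd_dna(80)
    a <- local_align(q, s)
    qa <- strsplit(a$query_aln, "")[[1]]
    sa <- strsplit(a$subject_aln, "")[[1]]
    # ungapped query characters reproduce the claimed query interval
    expect_equal(paste(qa[qa != "-"], collapse = ""),
                 substr(q, a$query_interval[1] + 1, a$query_interval[2]))
    expect_equal(paste(sa[sa != "-"], collapse = ""),
                 substr(s, a$subject_interval[1] + 1, a$subject_interval[2]))
    # column-wise rescoring reproduces the score
    col_score <- 0
    gap_dir <- ""
    for (k in seq_along(qa)) {
      if (qa[k] == "-" || sa[k] == "-") {
        dir <- if (qa[k] == "-") "q" else "s"
        col_score <- col_score + ifelse(gap_dir == dir, -2, -7)
        gap_dir <- dir
      } else {
        col_score <- col_score + ifelse(qa[k] == sa[k], 2, -3)
        gap_dir <- ""
      }
    }
    expect_equal(col_score, a$score)
  }
})

test_that("segment_map recovers chimera construction boundaries", {
  set.seed(64)
  subjA <- rnd_dna(200)
  subjB <- rnd_dna(300)
  mite <- paste0(substr(subjA, 1, 57), rnd_dna(100), substr(subjB, 50, 153))
  segs <- segment_map(mite, c(A = subjA, B = subjB),
                      min_score = 40, min_length = 30)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$subject_id, c("A", "B"))
  expect_lte(abs(segs$query_start[1] - 0), 3)
  expect_lte(abs(segs$query_end[1] - 57), 3)
  expect_lte(abs(segs$query_start[2] - 157), 3)
  expect_lte(abs(segs$query_end[2] - 261), 3)
  # segments never overlap on the query (masking)
  expect_lte(segs$query_end[1], segs$query_start[2])

  # negative control: an unrelated subject yields nothing at min_score 40
  expect_equal(nrow(segment_map(mite, c(R = rnd_dna(300)), min_score = 40)),
               0L)
})

test_that("master vs its deletion derivative yields two flanking segments", {
  m <- make_master(865, 24, c(300, 561), seed = 65)
  der <- paste0(substr(m$sequence, 1, 300), substr(m$sequence, 562, 865))
  # steep gap penalties forbid bridging the 261 bp deletion (see vignette)
  segs <- segment_map(m$sequence, c(derivative = der),
                      gap_open = -5, gap_extend = -5)
  expect_equal(nrow(segs), 2L)
  # boundaries within 3 bp (chance matches can extend one arm slightly
  # into the deletion window)
  expect_lte(abs(segs$query_start[1] - 0), 3)
  expect_lte(abs(segs$query_end[1] - 300), 3)
  expect_lte(abs(segs$query_start[2] - 561), 3)
  expect_lte(abs(segs$query_end[2] - 865), 3)
  expect_true(all(segs$p_distance < 0.02))
})

test_that("detect_tir finds constructed TIRs and respects thresholds", {
  m <- make_master(865, 24, c(300, 561), seed = 66)
  tc <- detect_tir(m$sequence)
  expect_gte(tc$length, 24)
  expect_equal(tc$mismatches, 0L)
  expect_equal(tc$arm5_interval, c(0L, tc$length))
  expect_equal(tc$arm3_interval, c(865L - tc$length, 865L))

  # 6 bp perfect terminal IR: called at min 6, not at min 10
  s <- paste0("ACGTTT", strrep("C", 20), "AAACGT")
  expect_null(detect_tir(s, min_tir_length = 10))
  t6 <- detect_tir(s, min_tir_length = 6)
  expect_equal(t6$length, 6L)
  expect_equal(t6$mismatches, 0L)

  expect_error(detect_tir("ACGT", min_tir_length = 10), "shorter")
})

test_that("detect_tir: random false-positive rate and revcomp invariance", {
  set.seed(67)
  fp <- vapply(1:100, function(i) {
    !is.null(detect_tir(rnd_dna(200), min_tir_length = 10))
  }, logical(1))
  expect_lt(mean(fp), 0.05)

  m <- make_master(400, 18, NULL, seed = 68)
  a <- detect_tir(m$sequence)
  b <- detect_tir(revcomp(m$sequence))
  expect_equal(a$length, b$length)
  expect_equal(a$mismatches, b$mismatches)
})

test_that("structure_string renders the element anatomy", {
  m <- make_master(865, 24, c(300, 561), seed = 69)
  tir <- detect_tir(m$sequence)
  segs <- segment_map(m$sequence,
                      c(core = substr(m$sequence, 100, 250)),
                      min_score = 40)
  s <- structure_string(segs, tir, 865)
  expect_match(s, "^TIR5\\|core:")
  expect_match(s, "\\|TIR3$")
})
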