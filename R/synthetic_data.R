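# Synthetic MITE amplification bursts with known ground truth.
#
# The generative model: a master element (a short non-coding DNA transposon
# with terminal inverted repeats) amplifies in a dated burst. Two variants
# circulate: the full element and an internal-deletion derivative lacking a
# fixed window of the master. Each inserted copy accumulates substitutions
# under the Jukes-Cantor model for its age, is flanked by a duplicated "TA"
# target site, and is reported as one or more (optionally fragmented)
# homology hit records against the master consensus.

#' Build a random master element with terminal inverted repeats
#'
#' The element core is uniform-random DNA; the 3' terminus is overwritten
#' with the reverse complement of the 5' terminus so the two ends form
#' perfect inverted repeats. An optional deletion window marks the segment
#' missing from the deletion-derivative variant.
#'
#' @param length element length in bp (default 865, a typical MITE).
#' @param tir_length terminal inverted repeat length in bp (default 24).
#' @param deletion_window integer pair `(start, end)`, 0-based half-open on
#'   the master, or `NULL` for no derivative variant. Must lie strictly
#'   between the TIRs.
#' @param seed optional RNG seed.
#' @return an object of class `master_element`: list with `id`, `sequence`,
#'   `tir_length`, `deletion_window`, `segment_map`.
#' @export
make_master <- function(length = 865L, tir_length = 24L,
                        deletion_window = c(300L, 561L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  tir_length <- as.integer(tir_length)
  if (tir_length < 0L || length < 2L * tir_length) {
    stopf("infeasible geometry: length %d cannot host two %d bp TIRs",
          length, tir_length)
  }
  if (!is.null(deletion_window)) {
    dw <- as.integer(deletion_window)
    if (length(dw) != 2L || dw[1] >= dw[2]) stopf("bad deletion_window")
    if (dw[1] < max(1L, tir_length) || dw[2] > length - max(1L, tir_length)) {
      stopf("deletion_window must lie strictly inside the element, between the TIRs")
    }
    if (length < 2L * tir_length + (dw[2] - dw[1])) {
      stopf("infeasible geometry: element too short for TIRs plus deletion window")
    }
    deletion_window <- dw
  }
  s <- sample(DNA_BASES, length, replace = TRUE)
  if (tir_length > 0L) {
    tir5 <- paste(s[seq_len(tir_length)], collapse = "")
    s[(length - tir_length + 1L):length] <- seq_chars(revcomp(tir5))
  }
  seg <- if (is.null(deletion_window)) {
    data.frame(label = c("TIR5", "core", "TIR3"),
               start = c(0L, tir_length, length - tir_length),
               end = c(tir_length, length - tir_length, length),
               stringsAsFactors = FALSE)
  } else {
    data.frame(label = c("TIR5", "core5", "internal", "core3", "TIR3"),
               start = c(0L, tir_length, deletion_window[1],
                         deletion_window[2], length - tir_length),
               end = c(tir_length, deletion_window[1], deletion_window[2],
                       length - tir_length, length),
               stringsAsFactors = FALSE)
  }
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  structure(list(id = "master", sequence = paste(s, collapse = ""),
                 tir_length = tir_length, deletion_window = deletion_window,
                 segment_map = seg),
            class = "master_element")
}

#' @export
print.master_element <- function(x, ...) {
  cat(sprintf("<master_element> %d bp, %d bp TIRs", nchar(x$sequence),
              x$tir_length))
  if (!is.null(x$deletion_window)) {
    cat(sprintf(", deletion window [%d,%d)", x$deletion_window[1],
                x$deletion_window[2]))
  }
  cat("\n")
  invisible(x)
}

#' Mutate a sequence under the Jukes-Cantor model
#'
#' Each site is independently replaced, with probability
#' `p = (3/4) (1 - exp(-(4/3) rate_s age))`, by a base drawn uniformly from
#' the three alternatives. `p` is the expected proportion of *observably*
#' different sites after `age` years at rate `rate_s`; multiple hits at one
#' site are thereby accounted for.
#'
#' @param sequence DNA string.
#' @param rate_s substitution rate, substitutions/site/year.
#' @param age elapsed time in years (0 allowed).
#' @return list with `sequence` (mutated string) and `substitutions`
#'   (number of changed sites).
#' @export
mutate_jc <- function(sequence, rate_s, age) {
  stopifnot(is.finite(rate_s * age), rate_s >= 0, age >= 0)
  p <- jc_expected_p(rate_s * age)
  chars <- seq_chars(toupper(sequence))
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  list(sequence = paste(chars, collapse = ""), substitutions = length(hit))
}

#' Expected proportion of differing sites under Jukes-Cantor
#'
#' @param d expected substitutions/site (`rate_s * age`).
#' @return `p = (3/4)(1 - exp(-(4/3) d))`.
#' @export
jc_expected_p <- function(d) 0.75 * (1 - exp(-4 / 3 * d))

#' Describe an amplification burst
#'
#' Defaults describe a Boreoeutheria-age MITE wave: the mammalian neutral
#' rate 2.2e-9 substitutions/site/year, a mean insertion age of 86 Myr
#' (placing mean copy-to-consensus divergence near 19%, the level typical
#' of old primate MITE families), copy counts of a few hundred per
#' variant, and moderate hit fragmentation.
#'
#' @param rate_s substitutions/site/year.
#' @param age_mean,age_sd mean and s.d. (years) of the Normal insertion-age
#'   distribution, truncated at 0.
#' @param n_copies named integer vector with entries `full` and
#'   `deletion_derivative`.
#' @param fragmentation_prob probability that a copy's hit record is split
#'   into collinear fragments.
#' @param max_fragments maximum pieces per fragmented copy.
#' @param seed RNG seed for the simulation.
#' @return an object of class `burst_model`.
#' @export
burst_model <- function(rate_s = 2.2e-9, age_mean = 86e6, age_sd = 10e6,
                        n_copies = c(full = 400L, deletion_derivative = 550L),
                        fragmentation_prob = 0.3, max_fragments = 3L,
                        seed = 1L) {
  stopifnot(rate_s > 0, age_mean > 0, age_sd >= 0,
            all(n_copies >= 0L), fragmentation_prob >= 0,
            fragmentation_prob <= 1, max_fragments >= 1L)
  if (is.null(names(n_copies))) {
    names(n_copies) <- c("full", "deletion_derivative")[seq_along(n_copies)]
  }
  structure(list(rate_s = rate_s, age_mean = age_mean, age_sd = age_sd,
                 n_copies = n_copies, fragmentation_prob = fragmentation_prob,
                 max_fragments = as.integer(max_fragments),
                 seed = as.integer(seed)),
            class = "burst_model")
}

# draw from Normal(mean, sd) truncated at 0 by resampling
rnorm_trunc0 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= 0)) {
    bad <- out <= 0
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

# cut [0, L) into k pieces separated by short removed gaps; returns a
# 2-col matrix of piece intervals (0-based half-open, copy coordinates)
cut_into_pieces <- function(L, k, min_piece = 30L, gap_range = c(5L, 30L)) {
  if (k <= 1L || L < k * min_piece + (k - 1L) * gap_range[2]) {
    return(cbind(0L, L))
  }
  cuts <- sort(sample(seq(min_piece, L - min_piece), k - 1L))
  # enforce spacing so no piece collapses below min_piece
  ok <- c(TRUE, diff(cuts) >= min_piece + gap_range[2])
  cuts <- cuts[ok]
  gaps <- sample(seq(gap_range[1], gap_range[2]),
                 length(cuts), replace = TRUE)
  starts <- c(0L, cuts + (gaps + 1L) %/% 2L)
  ends <- c(cuts - gaps %/% 2L, L)
  cbind(as.integer(starts), as.integer(ends))
}

#' Simulate a genome carrying a dated MITE burst
#'
#' Copies of the master (and, if a deletion window is defined, of its
#' deletion-derivative variant) are aged from a truncated Normal, mutated
#' under Jukes-Cantor, and inserted at distinct background positions on
#' either strand, each flanked by a duplicated `TA` target site. Hit
#' records against the master consensus are emitted per copy; with
#' probability `burst$fragmentation_prob` a copy's record is split into
#' collinear fragments separated by short gaps (the DNA itself stays
#' contiguous, emulating annotation fragmentation of diverged copies).
#' Synthetic genes (with mRNA/UTR/CDS sub-features) are laid down at
#' `gene_density`. The returned MSA holds each copy padded to master
#' coordinates, the deletion rendered as gaps: the alignment is exact by
#' construction.
#'
#' @param master a `master_element`.
#' @param burst a `burst_model`.
#' @param genome_length background (pre-insertion) genome length in bp.
#' @param gene_density fraction of the genome covered by gene bodies.
#' @param gene_length length of each synthetic gene.
#' @param flank_bp flank used for the `in_genic` truth flag.
#' @param contig name of the single output contig.
#' @return an object of class `mite_burst`: list with `genome` (named
#'   character), `truth` (data frame), `hits` (`mite_hits`), `msa` (named
#'   character, master-width rows), `genes` (`gene_features`), plus the
#'   `master` and `burst` used.
#' @export
simulate_burst <- function(master, burst = burst_model(),
                           genome_length = 2e6, gene_density = 0.13,
                           gene_length = 5000L, flank_bp = 5000L,
                           contig = "chr1") {
  set.seed(burst$seed)
  genome_length <- as.integer(genome_length)
  Lm <- nchar(master$sequence)
  dw <- master$deletion_window
  del_len <- if (is.null(dw)) 0L else dw[2] - dw[1]

  n_full <- as.integer(burst$n_copies["full"] %||% 0L)
  n_der <- as.integer(burst$n_copies["deletion_derivative"] %||% 0L)
  if (is.na(n_der)) n_der <- 0L
  if (is.na(n_full)) n_full <- 0L
  if (n_der > 0L && is.null(dw)) {
    stopf("master has no deletion_window; cannot simulate deletion derivatives")
  }
  n <- n_full + n_der

  if (genome_length < n * (Lm + 4L) || genome_length - 2L < n) {
    stopf("placement failure: genome_length %d too small for %d copies; increase genome_length",
          genome_length, n)
  }

  variant <- c(rep("full", n_full), rep("deletion_derivative", n_der))
  ages <- if (n) rnorm_trunc0(n, burst$age_mean, burst$age_sd) else numeric(0)
  strands <- if (n) sample(c("+", "-"), n, replace = TRUE) else character(0)
  slots <- if (n) sort(sample(seq_len(genome_length - 2L), n)) else integer(0)
  ord <- if (n) sample.int(n) else integer(0)   # which copy goes in which slot

  bg <- paste(sample(DNA_BASES, genome_length, replace = TRUE), collapse = "")

  copy_seq <- character(n)
  msa <- character(n)
  subs <- integer(n)
  for (i in seq_len(n)) {
    s <- master$sequence
    if (variant[i] == "deletion_derivative") {
      s <- paste0(substr(s, 1L, dw[1]), substr(s, dw[2] + 1L, Lm))
    }
    m <- mutate_jc(s, burst$rate_s, ages[i])
    copy_seq[i] <- m$sequence
    subs[i] <- m$substitutions
    msa[i] <- if (variant[i] == "full") m$sequence else {
      paste0(substr(m$sequence, 1L, dw[1]), strrep("-", del_len),
             substr(m$sequence, dw[1] + 1L, nchar(m$sequence)))
    }
  }
  copy_id <- sprintf("copy%04d", seq_len(n))
  names(msa) <- copy_id

  # assemble the genome: background chunks interleaved with TA|copy|TA
  chunks <- character(0)
  starts <- integer(n)   # final 0-based start of each copy (slot order)
  prev <- 0L
  offset <- 0L
  slot_copy <- ord       # copy index occupying slot j
  for (j in seq_len(n)) {
    i <- slot_copy[j]
    pos <- slots[j]
    chunks <- c(chunks, substr(bg, prev + 1L, pos), "TA",
                if (strands[i] == "-") revcomp(copy_seq[i]) else copy_seq[i],
                "TA")
    starts[i] <- pos + offset + 2L
    offset <- offset + nchar(copy_seq[i]) + 4L
    prev <- pos
  }
  chunks <- c(chunks, substr(bg, prev + 1L, genome_length))
  genome <- paste(chunks, collapse = "")
  ends <- starts + nchar(copy_seq)

  # hit records: copy-coordinate pieces mapped through the master
  hit_list <- vector("list", n)
  for (i in seq_len(n)) {
    Lc <- nchar(copy_seq[i])
    pieces <- cbind(0L, Lc)
    if (stats::runif(1) < burst$fragmentation_prob) {
      ks <- seq(2L, max(2L, burst$max_fragments))
      k <- ks[sample.int(length(ks), 1L)]
      pieces <- cut_into_pieces(Lc, k)
    }
    # copy coordinate -> master query coordinate segments
    segs <- if (variant[i] == "full" || is.null(dw)) {
      cbind(0L, Lc, 0L)      # start, end, query offset
    } else {
      rbind(c(0L, dw[1], 0L), c(dw[1], Lc, del_len))
    }
    rows <- list()
    for (pi in seq_len(nrow(pieces))) {
      for (si in seq_len(nrow(segs))) {
        cs <- max(pieces[pi, 1], segs[si, 1])
        ce <- min(pieces[pi, 2], segs[si, 2])
        if (cs >= ce) next
        qs <- cs + segs[si, 3]
        qe <- ce + segs[si, 3]
        if (strands[i] == "+") {
          ts <- starts[i] + cs; te <- starts[i] + ce
        } else {
          ts <- starts[i] + (Lc - ce); te <- starts[i] + (Lc - cs)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(query_id = master$id, target_id = contig,
                     query_start = qs, query_end = qe,
                     target_start = ts, target_end = te,
                     strand = strands[i],
                     percent_identity = 1 - subs[i] / max(Lc, 1L),
                     score = 2 * (ce - cs), evalue = 0,
                     stringsAsFactors = FALSE)
      }
    }
    hit_list[[i]] <- do.call(rbind, rows)
  }
  hits <- if (n) do.call(rbind, hit_list) else NULL
  hits <- if (is.null(hits)) empty_hits() else {
    validate_hits(hits); class(hits) <- c("mite_hits", "data.frame"); hits
  }

  genes <- simulate_genes(nchar(genome), gene_density, gene_length, contig)
  gene_rows <- genes[genes$feature_kind == "gene", , drop = FALSE]
  in_genic <- vapply(seq_len(n), function(i) {
    any(gene_rows$start - flank_bp < ends[i] &
          gene_rows$end + flank_bp > starts[i])
  }, logical(1))

  truth <- data.frame(
    copy_id = copy_id, variant = variant, age = ages,
    expected_p = jc_expected_p(burst$rate_s * ages),
    realized_substitutions = subs, contig = rep(contig, n),
    start = starts, end = ends, strand = strands, in_genic = in_genic,
    stringsAsFactors = FALSE
  )

  structure(list(genome = stats::setNames(genome, contig), truth = truth,
                 hits = hits, msa = msa, genes = genes, master = master,
                 burst = burst),
            class = "mite_burst")
}

# synthetic gene models: gene + mRNA + strand-aware 5'UTR/CDS/3'UTR
simulate_genes <- function(genome_length, gene_density, gene_length, contig) {
  n_genes <- floor(gene_density * genome_length / gene_length)
  if (n_genes < 1L) {
    return(gene_features(character(0), integer(0), integer(0)))
  }
  starts <- sort(sample(seq_len(genome_length - gene_length), n_genes))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  utr <- max(1L, as.integer(round(gene_length * 0.1)))
  rows <- lapply(seq_len(n_genes), function(g) {
    s <- starts[g]; e <- s + gene_length
    gid <- sprintf("g%04d", g)
    tid <- paste0(gid, ".t1")
    left <- if (strand[g] == "+") "five_prime_UTR" else "three_prime_UTR"
    right <- if (strand[g] == "+") "three_prime_UTR" else "five_prime_UTR"
    data.frame(
      contig = contig,
      start = c(s, s, s, s + utr, e - utr),
      end = c(e, e, s + utr, e - utr, e),
      strand = strand[g],
      feature_kind = c("gene", "mRNA", left, "CDS", right),
      id = c(gid, tid, paste0(tid, c(".utrL", ".cds", ".utrR"))),
      parent_id = c(NA, gid, tid, tid, tid),
      stringsAsFactors = FALSE
    )
  })
  g <- do.call(rbind, rows)
  gene_features(g$contig, g$start, g$end, g$strand, g$feature_kind,
                g$id, g$parent_id)
}

#' Write all artefacts of a simulated burst to a directory
#'
#' Emits genome FASTA, truth BED (+ TSV sidecar with ages), hits in both
#' BLAST-tabular and RepeatMasker dialects, the aligned copies FASTA and
#' the gene annotation (GFF3).
#'
#' @param sim a `mite_burst`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_burst <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_fasta(stats::setNames(sim$master$sequence, sim$master$id),
              file.path(dir, "master.fasta"))
  tr <- sim$truth
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", tr$contig, tr$start, tr$end,
                     tr$copy_id, tr$strand), file.path(dir, "truth.bed"))
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_blast_tab(sim$hits, file.path(dir, "hits.blast.tsv"))
  write_repeatmasker_out(
    sim$hits,
    query_lengths = stats::setNames(nchar(sim$master$sequence), sim$master$id),
    target_lengths = stats::setNames(nchar(sim$genome), names(sim$genome)),
    path = file.path(dir, "hits.rm.out"))
  if (length(sim$msa)) write_fasta(sim$msa, file.path(dir, "copies.aln.fasta"))
  write_gene_annotation(sim$genes, file.path(dir, "genes.gff3"), "gff3")
  invisible(dir)
}
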