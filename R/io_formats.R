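# Readers/writers for the external formats the pipeline touches. All
# coordinates are normalised here, once, to the package convention
# (0-based half-open, strand flag, start < end); nothing downstream ever
# sees a 1-based or inclusive coordinate.

GENE_FEATURE_KINDS <- c("gene", "mRNA", "five_prime_UTR", "CDS",
                        "three_prime_UTR", "lncRNA")

#' Construct and validate a table of homology hit records
#'
#' A hit record is one local alignment between a query element (usually a
#' repeat consensus) and a genomic target. Coordinates are 0-based
#' half-open; minus-strand hits keep `target_start < target_end` with
#' `strand == "-"`. Percent identity is a fraction in `[0, 1]`.
#'
#' @param query_id,target_id character vectors.
#' @param query_start,query_end,target_start,target_end integer positions,
#'   0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param percent_identity fraction of identical aligned bases.
#' @param score alignment score (bit score or Smith-Waterman score).
#' @param evalue expectation value, `>= 0` (`NA` when the source format
#'   has none).
#' @return a `data.frame` of class `mite_hits`.
#' @export
hit_records <- function(query_id, target_id, query_start, query_end,
                        target_start, target_end, strand,
                        percent_identity, score = NA_real_,
                        evalue = NA_real_) {
  n <- length(query_start)
  h <- data.frame(
    query_id = rep_len(as.character(query_id), n),
    target_id = rep_len(as.character(target_id), n),
    query_start = as.integer(query_start),
    query_end = rep_len(as.integer(query_end), n),
    target_start = rep_len(as.integer(target_start), n),
    target_end = rep_len(as.integer(target_end), n),
    strand = rep_len(as.character(strand), n),
    percent_identity = rep_len(as.numeric(percent_identity), n),
    score = rep_len(as.numeric(score), n),
    evalue = rep_len(as.numeric(evalue), n),
    stringsAsFactors = FALSE
  )
  validate_hits(h)
  class(h) <- c("mite_hits", "data.frame")
  h
}

validate_hits <- function(h) {
  if (nrow(h) == 0L) return(invisible(h))
  bad <- which(h$query_start >= h$query_end)
  if (length(bad)) stopf("hit %d: query_start >= query_end", bad[1])
  bad <- which(h$target_start >= h$target_end)
  if (length(bad)) stopf("hit %d: target_start >= target_end", bad[1])
  bad <- which(h$percent_identity < 0 | h$percent_identity > 1)
  if (length(bad)) stopf("hit %d: percent_identity outside [0,1]", bad[1])
  if (!all(h$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  bad <- which(!is.na(h$evalue) & h$evalue < 0)
  if (length(bad)) stopf("hit %d: negative evalue", bad[1])
  invisible(h)
}

empty_hits <- function() {
  hit_records(character(0), character(0), integer(0), integer(0),
              integer(0), integer(0), character(0), numeric(0))
}

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of sequences; names are the first
#'   whitespace-delimited token of each header. Case is preserved.
#'   An empty file yields an empty vector. Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate id %s in %s", dup[1], path)
  stats::setNames(as.character(ss), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read tabular (12-column) BLAST output
#'
#' Consumes the standard `outfmt 6` dialect: `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`. Input
#' coordinates are 1-based inclusive; `sstart > send` encodes a
#' minus-strand hit. Output coordinates are 0-based half-open with
#' `target_start < target_end` and the strand recorded; `pident` is
#' rescaled to a fraction.
#'
#' @param path file path.
#' @return a `mite_hits` data frame (see [hit_records()]).
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 12L)) {
    stopf("line %d: expected 12 tab-separated columns, found %d",
          which(n_col < 12L)[1], n_col[which(n_col < 12L)[1]])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  num_cols <- c(3:10, 11, 12)
  for (j in num_cols) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) stopf("line %d: non-numeric field '%s'",
                        which(is.na(v))[1], m[which(is.na(v))[1], j])
  }
  qstart <- as.integer(m[, 7]); qend <- as.integer(m[, 8])
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  if (any(qstart >= qend)) {
    stopf("line %d: degenerate query interval (qstart >= qend)",
          which(qstart >= qend)[1])
  }
  minus <- sstart > send
  hit_records(
    query_id = m[, 1], target_id = m[, 2],
    query_start = qstart - 1L, query_end = qend,
    target_start = ifelse(minus, send, sstart) - 1L,
    target_end = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    percent_identity = as.numeric(m[, 3]) / 100,
    score = as.numeric(m[, 12]),
    evalue = as.numeric(m[, 11])
  )
}

#' Write hits as 12-column tabular BLAST output
#'
#' Inverse of [read_blast_tab()]; `length`, `mismatch` and `gapopen` are
#' reconstructed approximately from the coordinates and identity.
#'
#' @param hits a `mite_hits` data frame.
#' @param path output path.
#' @export
write_blast_tab <- function(hits, path) {
  len <- hits$query_end - hits$query_start
  minus <- hits$strand == "-"
  sstart <- ifelse(minus, hits$target_end, hits$target_start + 1L)
  send <- ifelse(minus, hits$target_start + 1L, hits$target_end)
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t0\t%d\t%d\t%d\t%d\t%.2g\t%.1f",
                   hits$query_id, hits$target_id,
                   hits$percent_identity * 100, len,
                   as.integer(round((1 - hits$percent_identity) * len)),
                   hits$query_start + 1L, hits$query_end,
                   sstart, send,
                   ifelse(is.na(hits$evalue), 0, hits$evalue),
                   ifelse(is.na(hits$score), 0, hits$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read a RepeatMasker .out annotation file
#'
#' Parses the standard layout: three header lines followed by
#' whitespace-separated records. The strand column uses `C` for the
#' complement strand; the repeat-consensus coordinates are given as
#' `begin end (left)` on `+` and `(left) end begin` on `C`. The
#' divergence column is stored as `percent_identity = 1 - div/100`.
#' The trailing overlap-asterisk column, if present, is ignored.
#'
#' @param path file path.
#' @return a `mite_hits` data frame: `query_id` is the repeat consensus,
#'   `target_id` the genomic sequence.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 0L) {
    # standard files carry 2 header lines + 1 blank; tolerate header-only
    is_header <- grepl("^\\s*(SW|score|$)", lines[seq_len(min(3L, length(lines)))])
    lines <- lines[-seq_len(sum(is_header))]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_hits())
  recs <- strsplit(trimws(lines), "\\s+")
  parse_one <- function(f, lineno) {
    if (length(f) < 14L) stopf("line %d: truncated record", lineno)
    strand <- f[9]
    if (!strand %in% c("+", "C")) stopf("line %d: bad strand '%s'", lineno, strand)
    unparen <- function(x) {
      if (!grepl("^\\(\\d+\\)$", x)) {
        stopf("line %d: malformed parenthesized field '%s'", lineno, x)
      }
      as.integer(sub("^\\((\\d+)\\)$", "\\1", x))
    }
    if (strand == "+") {
      r_begin <- as.integer(f[12]); r_end <- as.integer(f[13]); unparen(f[14])
    } else {
      unparen(f[12]); r_end <- as.integer(f[13]); r_begin <- as.integer(f[14])
    }
    if (anyNA(c(r_begin, r_end))) stopf("line %d: non-numeric repeat coordinate", lineno)
    t_begin <- suppressWarnings(as.integer(f[6]))
    t_end <- suppressWarnings(as.integer(f[7]))
    if (anyNA(c(t_begin, t_end))) stopf("line %d: non-numeric target coordinate", lineno)
    div <- as.numeric(f[2])
    data.frame(query_id = f[10], target_id = f[5],
               query_start = r_begin - 1L, query_end = r_end,
               target_start = t_begin - 1L, target_end = t_end,
               strand = if (strand == "C") "-" else "+",
               percent_identity = 1 - div / 100,
               score = as.numeric(f[1]), evalue = NA_real_,
               stringsAsFactors = FALSE)
  }
  header_offset <- length(readLines(path)) - length(lines)
  out <- do.call(rbind, Map(parse_one, recs, header_offset + seq_along(recs)))
  validate_hits(out)
  class(out) <- c("mite_hits", "data.frame")
  out
}

#' Write hits as a RepeatMasker-style .out file
#'
#' Emits the dialect accepted by [read_repeatmasker_out()] (round-trip
#' safe for the fields the hit record carries).
#'
#' @param hits a `mite_hits` data frame.
#' @param query_lengths named integer vector of consensus lengths, used to
#'   fill the `(left)` fields.
#' @param target_lengths named integer vector of contig lengths.
#' @param path output path.
#' @export
write_repeatmasker_out <- function(hits, query_lengths, target_lengths, path) {
  hdr <- c(
    "   SW  perc perc perc  query     position in query    matching repeat      position in repeat",
    "score  div. del. ins.  sequence  begin  end   (left)  repeat   class/family  begin  end (left)  ID",
    "")
  q_left <- query_lengths[hits$query_id] - hits$query_end
  t_left <- target_lengths[hits$target_id] - hits$target_end
  div <- (1 - hits$percent_identity) * 100
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    if (hits$strand[i] == "+") {
      rep_cols <- sprintf("%d %d (%d)", hits$query_start[i] + 1L,
                          hits$query_end[i], q_left[i])
    } else {
      rep_cols <- sprintf("(%d) %d %d", q_left[i], hits$query_end[i],
                          hits$query_start[i] + 1L)
    }
    sprintf("%5.0f %5.1f  0.0  0.0  %s %d %d (%d) %s %s DNA/TcMar %s %d",
            ifelse(is.na(hits$score[i]), 0, hits$score[i]), div[i],
            hits$target_id[i], hits$target_start[i] + 1L, hits$target_end[i],
            t_left[i], if (hits$strand[i] == "-") "C" else "+",
            hits$query_id[i], rep_cols, i)
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Construct and validate a table of gene features
#'
#' @param contig,id,parent_id character vectors.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param feature_kind one of `gene`, `mRNA`, `five_prime_UTR`, `CDS`,
#'   `three_prime_UTR`, `lncRNA`.
#' @return a `data.frame` of class `gene_features`.
#' @export
gene_features <- function(contig, start, end, strand = ".",
                          feature_kind = "gene", id = NA_character_,
                          parent_id = NA_character_) {
  n <- length(start)
  g <- data.frame(contig = rep_len(as.character(contig), n),
                  start = as.integer(start),
                  end = rep_len(as.integer(end), n),
                  strand = rep_len(as.character(strand), n),
                  feature_kind = rep_len(as.character(feature_kind), n),
                  id = rep_len(as.character(id), n),
                  parent_id = rep_len(as.character(parent_id), n),
                  stringsAsFactors = FALSE)
  if (nrow(g)) {
    if (any(g$start >= g$end)) stopf("gene feature with start >= end")
    bad <- setdiff(unique(g$feature_kind), GENE_FEATURE_KINDS)
    if (length(bad)) stopf("unknown feature kind '%s'", bad[1])
  }
  class(g) <- c("gene_features", "data.frame")
  g
}

#' Read gene annotations from BED or GFF3
#'
#' BED input is taken as 0-based half-open (columns chrom, start, end,
#' name, and optionally score and strand); every BED record becomes a
#' `gene` feature. GFF3 input is 1-based inclusive and is shifted to the
#' package convention; `ID` and `Parent` attributes are captured. GFF3
#' types outside the supported set (`gene`, `mRNA`, `five_prime_UTR`,
#' `CDS`, `three_prime_UTR`, `lncRNA`/`lnc_RNA`) are skipped, with a
#' message giving the count.
#'
#' @param path file path.
#' @param dialect `"bed"` or `"gff3"`.
#' @return a `gene_features` data frame.
#' @export
read_gene_annotation <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = paste0("V", 1:6), fill = TRUE)
    strand <- if (ncol(tab) >= 6 && !all(is.na(tab$V6))) tab$V6 else "."
    id <- if (!all(is.na(tab$V4))) as.character(tab$V4) else NA_character_
    return(gene_features(contig = tab$V1, start = tab$V2, end = tab$V3,
                         strand = strand, feature_kind = "gene", id = id))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(gene_features(character(0), integer(0), integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9L)) {
    stopf("GFF3 line %d: fewer than 9 columns", which(lengths(f) < 9L)[1])
  }
  m <- do.call(rbind, lapply(f, `[`, 1:9))
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) stopf("GFF3: non-numeric coordinates")
  if (any(start1 > end1)) {
    stopf("GFF3 line %d: start > end", which(start1 > end1)[1])
  }
  type <- m[, 3]
  type[type == "lnc_RNA"] <- "lncRNA"
  keep <- type %in% GENE_FEATURE_KINDS
  if (any(!keep)) {
    message(sum(!keep), " GFF3 record(s) with unsupported feature kinds skipped")
  }
  attr_field <- function(attrs, key) {
    pat <- paste0("(^|;)", key, "=[^;]*")
    out <- rep(NA_character_, length(attrs))
    has <- grepl(pat, attrs)
    out[has] <- sub(paste0("^;?", key, "="), "",
                    regmatches(attrs, regexpr(pat, attrs)))
    out
  }
  gene_features(
    contig = m[keep, 1], start = start1[keep] - 1L, end = end1[keep],
    strand = m[keep, 7], feature_kind = type[keep],
    id = attr_field(m[keep, 9], "ID"),
    parent_id = attr_field(m[keep, 9], "Parent")
  )
}

#' Write gene annotations to BED4 or GFF3
#'
#' @param features a `gene_features` data frame.
#' @param path output path.
#' @param dialect `"bed"` (gene rows only, 0-based half-open) or `"gff3"`
#'   (all rows, 1-based inclusive, with `ID`/`Parent` attributes).
#' @export
write_gene_annotation <- function(features, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    g <- features[features$feature_kind == "gene", , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", g$contig, g$start, g$end,
                       ifelse(is.na(g$id), ".", g$id), g$strand), path)
  } else {
    attrs <- ifelse(is.na(features$id), ".", paste0("ID=", features$id))
    has_parent <- !is.na(features$parent_id)
    attrs[has_parent] <- paste0(attrs[has_parent], ";Parent=",
                                features$parent_id[has_parent])
    kind <- features$feature_kind
    writeLines(c("##gff-version 3",
                 sprintf("%s\tmitewave\t%s\t%d\t%d\t.\t%s\t.\t%s",
                         features$contig, kind, features$start + 1L,
                         features$end, features$strand, attrs)), path)
  }
  invisible(path)
}

#' Write a square PHYLIP distance matrix
#'
#' Names are truncated to 10 characters and uniquified with numeric
#' suffixes when truncation collides; the original-to-truncated mapping is
#' written to `<path>.names.tsv`.
#'
#' @param names sequence names (length n).
#' @param matrix square symmetric numeric matrix with a zero diagonal.
#' @param path output path.
#' @export
write_phylip_distances <- function(names, matrix, path) {
  n <- length(names)
  if (!is.matrix(matrix) || nrow(matrix) != n || ncol(matrix) != n) {
    stopf("matrix must be %d x %d", n, n)
  }
  if (max(abs(matrix - t(matrix))) > 1e-9) stopf("matrix is not symmetric")
  short <- substr(names, 1L, 10L)
  while (anyDuplicated(short)) {
    d <- duplicated(short) | duplicated(short, fromLast = TRUE)
    idx <- stats::ave(seq_along(short), short, FUN = seq_along)
    short[d] <- paste0(substr(short[d], 1L, 10L - nchar(idx[d]) - 1L), "_", idx[d])
  }
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(short[i], width = -10),
                      paste(sprintf("%.6f", matrix[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  utils::write.table(data.frame(short = short, original = names),
                     paste0(path, ".names.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' Inverse of [write_phylip_distances()]; restores original names from the
#' sidecar mapping file when present.
#'
#' @param path file path.
#' @return list with `names` and `matrix`.
#' @export
read_phylip_distances <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  nm <- character(n)
  mat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nm[i] <- trimws(substr(lines[i + 1L], 1L, 10L))
    mat[i, ] <- as.numeric(strsplit(trimws(substr(lines[i + 1L], 11L,
                                                  nchar(lines[i + 1L]))),
                                    "\\s+")[[1]])
  }
  sidecar <- paste0(path, ".names.tsv")
  if (file.exists(sidecar)) {
    map <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    nm <- map$original[match(nm, map$short)]
  }
  list(names = nm, matrix = mat)
}
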