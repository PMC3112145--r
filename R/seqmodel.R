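## Core domain types and readers/writers: nucleotide sequences, intervals,
## gene models and exon-phase profiles.

#' Construct a nucleotide sequence object
#'
#' @param id sequence label.
#' @param residues nucleotide string over A/C/G/T/N (case-insensitive).
#' @param description optional free-text description.
#' @return an object of class `NucSequence` with fields `id`, `seq`,
#'   `description`.
#' @export
nuc_sequence <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  res <- toupper(as.character(residues))
  if (length(res) != 1L || nchar(res) < 1L)
    stop("sequence '", id, "': length must be >= 1")
  bad <- regexpr("[^ACGTN]", res)
  if (bad > 0L)
    stop("sequence '", id, "': illegal residue '",
         substr(res, bad, bad), "' at position ", bad)
  structure(list(id = id, seq = res, description = description),
            class = "NucSequence")
}

#' @export
print.NucSequence <- function(x, ...) {
  cat(sprintf("<NucSequence %s: %d bp>\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' @export
length.NucSequence <- function(x) nchar(x$seq)

as_seq_string <- function(x) {
  if (inherits(x, "NucSequence")) x$seq else toupper(as.character(x))
}

#' Read a FASTA file of nucleotide sequences
#'
#' Records are returned in file order; lowercase residues are normalized to
#' uppercase; any residue outside A/C/G/T/N raises an error naming the
#' offending record and position.
#'
#' @param path FASTA file.
#' @return list of [nuc_sequence()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty input: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  desc <- sub("^\\S+\\s*", "", names(ss))
  out <- lapply(seq_along(ss), function(i)
    nuc_sequence(ids[i], as.character(ss[[i]]), desc[i]))
  pa_log("read_fasta: ", length(out), " record(s) from ", path)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs list of `NucSequence` (or named character vector).
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    seqs <- Map(nuc_sequence, names(seqs), seqs)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    hdr <- if (nzchar(s$description)) paste(s$id, s$description) else s$id
    writeLines(paste0(">", hdr), con)
    n <- nchar(s$seq)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Construct an interval table
#'
#' Internal convention is 0-based half-open on the plus strand; minus-strand
#' features carry `strand = "-"`.
#'
#' @param seq_id,start,end,strand,label vectors, recycled to common length.
#' @return data.frame of class `Interval`.
#' @export
intervals <- function(seq_id, start, end, strand = "+", label = "") {
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand), label = as.character(label),
                   stringsAsFactors = FALSE)
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("malformed interval at row ", bad[1], ": start=", df$start[bad[1]],
         " end=", df$end[bad[1]])
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  class(df) <- c("Interval", "data.frame")
  df
}

#' Parse NCBI-style span strings
#'
#' Accepts strings such as `"NC_000023: complementary 151952946..151957859"`
#' (1-based inclusive; `complementary` marks the minus strand; the two-dot
#' ellipsis may be ASCII `..` or Unicode). Conversion to the internal 0-based
#' half-open convention subtracts one from the start.
#'
#' @param x character vector of spans.
#' @return `Interval` data.frame.
#' @export
parse_ncbi_span <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec(
    "^([^:]+):\\s*(complementary\\s+)?([0-9]+)\\s*(?:\\.\\.|‥)\\s*([0-9]+)$",
    x))
  out <- lapply(seq_along(m), function(i) {
    g <- m[[i]]
    if (length(g) == 0L) stop("cannot parse NCBI span: '", x[i], "'")
    start1 <- as.numeric(g[4]); end1 <- as.numeric(g[5])
    if (start1 > end1) stop("malformed span (start > end): '", x[i], "'")
    data.frame(seq_id = trimws(g[2]), start = start1 - 1, end = end1,
               strand = if (nzchar(g[3])) "-" else "+", label = "",
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  intervals(df$seq_id, df$start, df$end, df$strand, df$label)
}

#' Format intervals as NCBI-style spans
#'
#' Inverse of [parse_ncbi_span()] (round-trip identity).
#'
#' @param iv `Interval` data.frame.
#' @return character vector of span strings.
#' @export
format_ncbi_span <- function(iv) {
  paste0(iv$seq_id, ": ", ifelse(iv$strand == "-", "complementary ", ""),
         format(iv$start + 1, scientific = FALSE, trim = TRUE), "..",
         format(iv$end, scientific = FALSE, trim = TRUE))
}

#' Read intervals from BED or NCBI-span files
#'
#' @param path input file. BED: whitespace-separated
#'   `chrom start end [name [score [strand]]]`, already 0-based half-open.
#'   `ncbi_span`: one span string per line (see [parse_ncbi_span()]).
#' @param dialect `"bed"` or `"ncbi_span"`.
#' @return `Interval` data.frame in the internal convention.
#' @export
read_intervals <- function(path, dialect = c("bed", "ncbi_span")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "ncbi_span") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty input: ", path)
    iv <- parse_ncbi_span(lines)
  } else {
    tb <- read.table(path, header = FALSE, sep = "", quote = "",
                     comment.char = "#", stringsAsFactors = FALSE)
    if (nrow(tb) == 0L) stop("empty input: ", path)
    if (ncol(tb) < 3L) stop("BED needs >= 3 columns: ", path)
    iv <- intervals(tb[[1]], tb[[2]], tb[[3]],
                    strand = if (ncol(tb) >= 6) tb[[6]] else "+",
                    label = if (ncol(tb) >= 4) tb[[4]] else "")
  }
  pa_log("read_intervals: ", nrow(iv), " interval(s) from ", path)
  iv
}

#' Write intervals as BED
#'
#' @param iv `Interval` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  out <- data.frame(iv$seq_id,
                    format(iv$start, scientific = FALSE, trim = TRUE),
                    format(iv$end, scientific = FALSE, trim = TRUE),
                    ifelse(nzchar(iv$label), iv$label, "."),
                    0L, iv$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a gene model
#'
#' @param gene_id gene label.
#' @param exon_sizes bp sizes of coding exons, 5' to 3' on the coding strand.
#'   `NA` marks an exon position present in a cross-species comparison but
#'   untranslated/unshared in this model ("not comparable").
#' @param exons optional `Interval` data.frame of exon coordinates
#'   (non-overlapping, ordered).
#' @return object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, exon_sizes, exons = NULL) {
  sizes <- as.numeric(exon_sizes)
  if (!length(sizes)) stop("gene model needs >= 1 exon")
  if (any(!is.na(sizes) & sizes < 1)) stop("exon sizes must be >= 1")
  if (!is.null(exons)) {
    o <- order(exons$start)
    if (any(exons$start[o][-1] < exons$end[o][-nrow(exons)]))
      stop("exons overlap in gene model '", gene_id, "'")
  }
  structure(list(gene_id = gene_id, exon_sizes = sizes, exons = exons),
            class = "GeneModel")
}

#' Read gene models from a TSV table
#'
#' Expected columns: `gene_id`, `exon` (index), `size` (bp; NA allowed for
#' non-comparable exon slots), `coding` (logical/0-1; non-coding rows are
#' dropped).
#'
#' @param path TSV file with header.
#' @return named list of `GeneModel` objects.
#' @export
read_gene_models <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", "-", ""))
  need <- c("gene_id", "exon", "size", "coding")
  if (!all(need %in% names(tb)))
    stop("gene-model table must have columns: ", paste(need, collapse = ", "))
  tb <- tb[as.logical(tb$coding) %in% TRUE, ]
  pa_log("read_gene_models: ", nrow(tb), " coding exon row(s) from ", path)
  models <- lapply(split(tb, tb$gene_id), function(g) {
    g <- g[order(g$exon), ]
    gene_model(g$gene_id[1], g$size)
  })
  models[unique(tb$gene_id)]
}

#' Exon phases along a coding sequence
#'
#' The phase entering exon *i* equals the phase leaving exon *i - 1*; the
#' phase leaving exon *i* is `(start_phase + size) mod 3`. Exons with `NA`
#' size propagate `NA` phases ("not comparable") without breaking the
#' running phase of downstream exons only when they begin the profile;
#' an internal `NA` makes all downstream phases `NA`.
#'
#' @param model a `GeneModel`, or a numeric vector of exon sizes.
#' @param initial_phase phase (0, 1 or 2) entering the first listed exon.
#' @return data.frame with columns `exon`, `size`, `start_phase`,
#'   `end_phase`.
#' @export
exon_phases <- function(model, initial_phase = 0L) {
  sizes <- if (inherits(model, "GeneModel")) model$exon_sizes
           else as.numeric(model)
  if (!initial_phase %in% 0:2) stop("initial_phase must be 0, 1 or 2")
  n <- length(sizes)
  sp <- ep <- rep(NA_integer_, n)
  phase <- as.integer(initial_phase)
  for (i in seq_len(n)) {
    if (is.na(phase) || is.na(sizes[i])) {
      if (!is.na(sizes[i]) && is.na(phase)) phase <- NA_integer_
      sp[i] <- if (is.na(sizes[i])) NA_integer_ else phase
      phase <- NA_integer_
      next
    }
    sp[i] <- phase
    phase <- (phase + as.integer(sizes[i])) %% 3L
    ep[i] <- phase
  }
  data.frame(exon = seq_len(n), size = sizes,
             start_phase = sp, end_phase = ep)
}

#' Compare exon-phase profiles across species
#'
#' @param profiles named list; each element either the data.frame returned by
#'   [exon_phases()] or a two-column matrix/data.frame of
#'   (start_phase, end_phase) per exon. Profiles are compared positionally;
#'   an exon slot is "shared" when every profile has non-`NA` phases there.
#' @return list with `per_exon` (data.frame: exon, shared, identical),
#'   `conserved` (all shared exons agree), and `mismatches` (exon indices).
#' @export
compare_phase_profiles <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop("need >= 2 phase profiles")
  get_mat <- function(p) {
    if (is.data.frame(p) && all(c("start_phase", "end_phase") %in% names(p)))
      cbind(p$start_phase, p$end_phase)
    else as.matrix(p)
  }
  mats <- lapply(profiles, get_mat)
  n <- max(vapply(mats, nrow, 1L))
  pad <- function(m) rbind(m, matrix(NA_integer_, n - nrow(m), 2L))
  mats <- lapply(mats, pad)
  shared <- identical_at <- logical(n)
  for (i in seq_len(n)) {
    ph <- t(vapply(mats, function(m) m[i, ], numeric(2)))
    shared[i] <- !anyNA(ph)
    identical_at[i] <- shared[i] &&
      all(ph[, 1] == ph[1, 1]) && all(ph[, 2] == ph[1, 2])
  }
  per_exon <- data.frame(exon = seq_len(n), shared = shared,
                         identical = ifelse(shared, identical_at, NA))
  list(per_exon = per_exon,
       conserved = all(identical_at[shared]),
       mismatches = which(shared & !identical_at))
}
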