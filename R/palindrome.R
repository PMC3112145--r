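## Self-comparison (dot-matrix) scanning, inverted-repeat/palindrome calling,
## similarity color binning, and marker-based orthology of duplicated units.
## All coordinates are 0-based half-open on the input sequence.

## k-mer starts (1-based) and strings; k-mers containing N are dropped
seq_kmers <- function(s, k) {
  L <- nchar(s)
  starts <- 1:(L - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("N", km, fixed = TRUE)
  list(starts = starts[ok], kmers = km[ok])
}

## chain sorted seed starts on one diagonal into runs with gaps <= max_gap
chain_runs <- function(starts, k, max_gap) {
  o <- order(starts)
  s <- starts[o]
  brk <- which(diff(s) > max_gap + k)
  grp <- cumsum(c(1L, seq_along(s)[-1] %in% (brk + 1L)))
  lapply(split(s, grp), range)
}

#' Self-comparison of a sequence by exact k-word seeding
#'
#' Finds direct and inverted repeat segments within one sequence: exact
#' k-word matches on the forward and reverse-complement strand are chained
#' into collinear (same-diagonal) runs with inter-seed gaps up to `max_gap`,
#' extended without gaps under an x-drop rule, and reported when the chained
#' span reaches `min_segment`. The trivial self-diagonal is excluded, and
#' each off-diagonal match is reported once with the query interval upstream
#' of the subject interval. Identity is computed base-by-base on the
#' extended, gap-free span.
#'
#' @param seq a `NucSequence` or nucleotide string.
#' @param k seed word size (>= 8; default 12).
#' @param min_segment minimum chained segment span in bp.
#' @param max_gap maximum unmatched gap between chained seeds (default 2k).
#' @param max_kmer_freq words occurring more often than this are skipped
#'   (cheap low-complexity guard).
#' @return data.frame of `MatchSegment` rows: `q_start`, `q_end`, `s_start`,
#'   `s_end` (0-based half-open), `orientation` ("direct"/"inverted"),
#'   `length`, `identity`.
#' @export
self_compare <- function(seq, k = 12L, min_segment = 300L,
                         max_gap = 2L * k, max_kmer_freq = 10L) {
  if (k < 8L) stop("seed word size k must be >= 8")
  s <- as_seq_string(seq)
  L <- nchar(s)
  if (L < 2L * k) stop("sequence shorter than 2k")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  rc <- revcomp(s)
  rch <- strsplit(rc, "", fixed = TRUE)[[1]]
  fw <- seq_kmers(s, k)
  rv <- seq_kmers(rc, k)

  segs <- list()
  add_seg <- function(q1, q2, s1, s2, orient) {
    ## identity over equal-length spans, inverted compares vs revcomp
    len <- q2 - q1 + 1L
    qv <- ch[q1:q2]
    sv <- if (orient == "direct") ch[s1:s2]
          else rev(chartr("ACGTN", "TGCAN", ch[s1:s2]))
    idt <- sum(qv == sv) / len
    data.frame(q_start = q1 - 1L, q_end = q2, s_start = s1 - 1L, s_end = s2,
               orientation = orient, length = len, identity = idt,
               stringsAsFactors = FALSE)
  }

  ## ---- direct matches: duplicate forward k-mers -------------------------
  grp <- split(fw$starts, fw$kmers)
  grp <- grp[lengths(grp) > 1L & lengths(grp) <= max_kmer_freq]
  if (length(grp)) {
    prs <- do.call(cbind, lapply(grp, function(g) combn(sort(g), 2L)))
    diag_id <- prs[2, ] - prs[1, ]
    for (d in unique(diag_id)) {
      ii <- prs[1, diag_id == d]
      for (rng in chain_runs(ii, k, max_gap)) {
        q1 <- rng[1]; q2 <- rng[2] + k - 1L
        ext <- extend_diag(ch, ch, q1, q2, d, L, L)
        q1 <- ext[1]; q2 <- ext[2]
        if (q2 - q1 + 1L >= min_segment)
          segs[[length(segs) + 1L]] <-
            add_seg(q1, q2, q1 + d, q2 + d, "direct")
      }
    }
  }

  ## ---- inverted matches: forward k-mers equal to reverse-strand k-mers --
  common <- intersect(fw$kmers, rv$kmers)
  if (length(common)) {
    fidx <- split(fw$starts, fw$kmers)[common]
    ridx <- split(rv$starts, rv$kmers)[common]
    pairs_i <- integer(0); pairs_j <- integer(0)
    for (w in seq_along(common)) {
      fi <- fidx[[w]]; rj <- ridx[[w]]
      if (length(fi) * length(rj) > max_kmer_freq^2) next
      ## rc-coordinate r maps to original start j = L - r - k + 2
      jj <- L - rj - k + 2L
      eg <- expand.grid(i = fi, j = jj)
      keep <- eg$i + k - 1L < eg$j   # canonical: query strictly upstream
      pairs_i <- c(pairs_i, eg$i[keep]); pairs_j <- c(pairs_j, eg$j[keep])
    }
    if (length(pairs_i)) {
      anti <- pairs_i + pairs_j      # k-mer start anti-diagonal, constant
      for (d in unique(anti)) {
        sel <- anti == d
        ii <- pairs_i[sel]
        cbase <- d + k - 1L          # base-level pairing: i <-> cbase - i
        for (rng in chain_runs(ii, k, max_gap)) {
          q1 <- rng[1]; q2 <- rng[2] + k - 1L
          ext <- extend_antidiag(ch, q1, q2, cbase, L)
          q1 <- ext[1]; q2 <- ext[2]
          s1 <- cbase - q2; s2 <- cbase - q1
          if (q2 - q1 + 1L >= min_segment && q2 < s1)
            segs[[length(segs) + 1L]] <-
              add_seg(q1, q2, s1, s2, "inverted")
        }
      }
    }
  }
  out <- if (length(segs)) do.call(rbind, segs)
         else data.frame(q_start = numeric(0), q_end = numeric(0),
                         s_start = numeric(0), s_end = numeric(0),
                         orientation = character(0), length = numeric(0),
                         identity = numeric(0), stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("MatchSegment", "data.frame")
  out
}

## extend [q1,q2] along diagonal shift d (direct repeat; subject = q + d)
extend_diag <- function(ch, ch2, q1, q2, d, Lq, Ls) {
  score <- 0; best <- 0; best_i <- q1
  i <- q1 - 1L
  while (i >= 1L && i + d >= 1L) {
    score <- score + if (ch[i] == ch2[i + d]) 1 else -3
    if (score > best) { best <- score; best_i <- i }
    if (best - score > 12) break
    i <- i - 1L
  }
  new_q1 <- min(q1, best_i)
  score <- 0; best <- 0; best_i <- q2
  i <- q2 + 1L
  while (i <= Lq && i + d <= Ls) {
    score <- score + if (ch[i] == ch2[i + d]) 1 else -3
    if (score > best) { best <- score; best_i <- i }
    if (best - score > 12) break
    i <- i + 1L
  }
  c(new_q1, max(q2, best_i))
}

## extend [q1,q2] along anti-diagonal c = i + j (inverted; subject base at
## j = c - i must equal complement of query base at i)
extend_antidiag <- function(ch, q1, q2, cdiag, L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  score <- 0; best <- 0; best_i <- q1
  i <- q1 - 1L
  while (i >= 1L && cdiag - i <= L) {
    j <- cdiag - i
    score <- score + if (!is.na(comp[ch[i]]) && ch[j] == comp[[ch[i]]]) 1
                     else -3
    if (score > best) { best <- score; best_i <- i }
    if (best - score > 12) break
    i <- i - 1L
  }
  new_q1 <- min(q1, best_i)
  score <- 0; best <- 0; best_i <- q2
  i <- q2 + 1L
  while (cdiag - i >= 1L && i <= L && i < cdiag - i) {
    j <- cdiag - i
    score <- score + if (!is.na(comp[ch[i]]) && ch[j] == comp[[ch[i]]]) 1
                     else -3
    if (score > best) { best <- score; best_i <- i }
    if (best - score > 12) break
    i <- i + 1L
  }
  c(new_q1, max(q2, best_i))
}

#' Similarity color bin
#'
#' Dot-matrix similarity classes: identity > 0.95 is `red`; (0.90, 0.95] is
#' `orange`; (0.85, 0.90] is `green`; <= 0.85 is `blue` (half-open
#' convention at each boundary).
#'
#' @param identity numeric vector of identities in \[0, 1\].
#' @return character vector of color classes.
#' @export
bin_similarity <- function(identity) {
  if (any(is.na(identity)) || any(identity < 0 | identity > 1))
    stop("identity must be in [0, 1]")
  out <- rep("blue", length(identity))
  out[identity > 0.85] <- "green"
  out[identity > 0.90] <- "orange"
  out[identity > 0.95] <- "red"
  out
}

#' Call palindromes from self-comparison segments
#'
#' Inverted segments whose query/subject intervals are disjoint and
#' mirror-ordered are clustered by anti-diagonal (within `diag_tol`) and
#' merged into arm pairs; the loop is the gap between arms. Arm identity is
#' recomputed base-by-base over the merged arm spans against the
#' reverse-complemented partner arm (anchored on the dominant anti-diagonal
#' when span lengths differ). Calls are sorted by arm length and overlapping
#' calls resolved to the longest.
#'
#' @param segments `MatchSegment` data.frame from [self_compare()] on one
#'   sequence.
#' @param seq the sequence the segments came from.
#' @param min_arm minimum arm length in bp.
#' @param min_identity minimum arm identity.
#' @param diag_tol anti-diagonal clustering tolerance in bp.
#' @return data.frame of `PalindromeCall` rows: `arm1_start`, `arm1_end`,
#'   `loop_start`, `loop_end`, `arm2_start`, `arm2_end`, `arm_length`,
#'   `arm_identity`, `center` (loop midpoint, 0-based).
#' @export
detect_palindromes <- function(segments, seq, min_arm = 1000L,
                               min_identity = 0.8, diag_tol = 200L) {
  empty <- data.frame(arm1_start = numeric(0), arm1_end = numeric(0),
                      loop_start = numeric(0), loop_end = numeric(0),
                      arm2_start = numeric(0), arm2_end = numeric(0),
                      arm_length = numeric(0), arm_identity = numeric(0),
                      center = numeric(0))
  inv <- segments[segments$orientation == "inverted" &
                    segments$q_end <= segments$s_start, , drop = FALSE]
  if (!nrow(inv)) return(empty)
  s <- as_seq_string(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  anti <- inv$q_start + inv$s_end   # 0-based anti-diagonal (q_start + s_end)
  o <- order(anti)
  cl <- cumsum(c(1L, diff(anti[o]) > diag_tol))
  calls <- lapply(split(o, cl), function(rows) {
    g <- inv[rows, , drop = FALSE]
    a1 <- c(min(g$q_start), max(g$q_end))
    a2 <- c(min(g$s_start), max(g$s_end))
    if (a1[2] > a2[1]) return(NULL)      # arms must stay disjoint
    len1 <- a1[2] - a1[1]; len2 <- a2[2] - a2[1]
    ## identity: elementwise when equal lengths, else anchor on the
    ## weighted dominant anti-diagonal and compare the overlapping span
    q <- ch[(a1[1] + 1):a1[2]]
    t2 <- rev(chartr("ACGTN", "TGCAN", ch[(a2[1] + 1):a2[2]]))
    nmin <- min(length(q), length(t2))
    idt <- sum(q[seq_len(nmin)] == t2[seq_len(nmin)]) / nmin
    arm_len <- min(len1, len2)
    if (arm_len < min_arm || idt < min_identity) return(NULL)
    data.frame(arm1_start = a1[1], arm1_end = a1[2],
               loop_start = a1[2], loop_end = a2[1],
               arm2_start = a2[1], arm2_end = a2[2],
               arm_length = arm_len, arm_identity = idt,
               center = (a1[2] + a2[1]) / 2)
  })
  calls <- do.call(rbind, Filter(Negate(is.null), calls))
  if (is.null(calls) || !nrow(calls)) return(empty)
  ## longest-first resolution of overlapping calls
  calls <- calls[order(-calls$arm_length), , drop = FALSE]
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (calls$arm1_start[i] < calls$arm2_end[j] &&
          calls$arm2_end[i] > calls$arm1_start[j]) { keep[i] <- FALSE; break }
    }
  }
  calls <- calls[keep, , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("PalindromeCall", "data.frame")
  calls
}

#' Construct a duplicated unit
#'
#' @param label unit name (e.g. `"h1"`).
#' @param start,end 0-based half-open coordinates on the host sequence.
#' @param markers character vector of cladistic-marker labels (shared
#'   transposable-element insertions) contained in the unit.
#' @return object of class `DuplicatedUnit`.
#' @export
duplicated_unit <- function(label, start, end, markers = character(0)) {
  stopifnot(start >= 0, end > start)
  structure(list(label = label, start = start, end = end,
                 markers = unique(as.character(markers))),
            class = "DuplicatedUnit")
}

#' Marker-based orthology scores between duplicated units
#'
#' Scores every cross-species unit pair by the Jaccard index of their
#' cladistic-marker sets, then assigns one-to-one orthologs greedily by
#' descending score, breaking ties by positional order. Units with empty
#' marker sets score 0 against everything and are flagged.
#'
#' @param units_a,units_b lists of [duplicated_unit()] (marker vocabularies
#'   must be comparable across the two lists).
#' @return list: `scores` (matrix), `assignment` (data.frame `unit_a`,
#'   `unit_b`, `jaccard`), `unassigned_a`, `unassigned_b`,
#'   `empty_marker_units`.
#' @export
unit_orthology_scores <- function(units_a, units_b) {
  la <- vapply(units_a, `[[`, "", "label")
  lb <- vapply(units_b, `[[`, "", "label")
  sc <- matrix(0, length(units_a), length(units_b),
               dimnames = list(la, lb))
  for (i in seq_along(units_a)) for (j in seq_along(units_b)) {
    ma <- units_a[[i]]$markers; mb <- units_b[[j]]$markers
    u <- length(union(ma, mb))
    sc[i, j] <- if (u == 0L) 0 else length(intersect(ma, mb)) / u
  }
  empty <- c(la[lengths(lapply(units_a, `[[`, "markers")) == 0L],
             lb[lengths(lapply(units_b, `[[`, "markers")) == 0L])
  free_a <- seq_along(la); free_b <- seq_along(lb)
  rows <- list()
  work <- sc
  while (length(free_a) && length(free_b)) {
    best <- max(work[free_a, free_b, drop = FALSE])
    if (best <= 0) break
    ## ties broken by positional (row-major) order
    hit <- which(outer(seq_along(la) %in% free_a,
                       seq_along(lb) %in% free_b) & work == best,
                 arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    rows[[length(rows) + 1L]] <-
      data.frame(unit_a = la[hit[1]], unit_b = lb[hit[2]],
                 jaccard = best, stringsAsFactors = FALSE)
    free_a <- setdiff(free_a, hit[1]); free_b <- setdiff(free_b, hit[2])
  }
  assignment <- if (length(rows)) do.call(rbind, rows)
                else data.frame(unit_a = character(0), unit_b = character(0),
                                jaccard = numeric(0))
  list(scores = sc, assignment = assignment,
       unassigned_a = la[free_a], unassigned_b = lb[free_b],
       empty_marker_units = unname(empty))
}
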