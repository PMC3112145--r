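## Independent brute-force oracles and small construction helpers shared by
## the test files. The oracle code deliberately shares nothing with the
## package implementation beyond the genetic code itself.

GC_TABLE <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")

oracle_translate <- function(codon) unname(GC_TABLE[codon])

## synonymous site count of one codon: per position, fraction of non-stop
## single-base neighbors that keep the amino acid
oracle_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    neigh <- character(0)
    for (b in setdiff(BASES, ch[pos])) {
      cc <- ch; cc[pos] <- b
      neigh <- c(neigh, paste(cc, collapse = ""))
    }
    keep <- neigh[oracle_translate(neigh) != "*"]
    if (length(keep))
      s <- s + mean(oracle_translate(keep) == oracle_translate(codon))
  }
  s
}

## enumerate every order of the differing positions recursively; each step
## classifies the change as synonymous/nonsynonymous; paths through stop
## codons are dropped (all paths used if every one is blocked)
oracle_paths <- function(c1, c2, allow_stop = FALSE) {
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  walk <- function(cur, left) {
    if (!length(left)) return(list(c(0, 0)))
    out <- list()
    for (p in left) {
      nxt <- cur; nxt[p] <- v2[p]
      codon_next <- paste(nxt, collapse = "")
      if (!allow_stop && oracle_translate(codon_next) == "*" &&
          codon_next != c2) next
      step <- if (oracle_translate(paste(cur, collapse = "")) ==
                    oracle_translate(codon_next)) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, setdiff(left, p)))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  res <- walk(v1, which(v1 != v2))
  if (!length(res)) res <- oracle_paths(c1, c2, allow_stop = TRUE)
  res
}

oracle_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  res <- oracle_paths(c1, c2)
  Reduce(`+`, res) / length(res)
}

## full Nei-Gojobori oracle over two ungapped coding sequences
oracle_ng <- function(cds1, cds2) {
  n <- nchar(cds1) / 3
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(n)) {
    a <- substr(cds1, 3 * i - 2, 3 * i)
    b <- substr(cds2, 3 * i - 2, 3 * i)
    S <- S + (oracle_sites(a) + oracle_sites(b)) / 2
    d <- oracle_diffs(a, b)
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  c(S = S, N = 3 * n - S, Sd = Sd, Nd = Nd)
}

SENSE_CODONS <- names(GC_TABLE)[GC_TABLE != "*" & !grepl("[^ACGT]", names(GC_TABLE))]

random_sense_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

## apply k single-nucleotide changes of a given class at distinct codons
plant_changes <- function(cds, k, class = c("synonymous", "nonsynonymous"),
                          codon_pool = seq_len(nchar(cds) / 3)) {
  class <- match.arg(class)
  v <- strsplit(cds, "")[[1]]
  done <- integer(0)
  pool <- sample(codon_pool)
  for (cod in pool) {
    if (length(done) >= k) break
    o <- (cod - 1) * 3
    hit <- FALSE
    for (pos in sample(1:3)) {
      for (b in sample(setdiff(BASES, v[o + pos]))) {
        w <- v[(o + 1):(o + 3)]; w[pos] <- b
        cand <- paste(w, collapse = "")
        old <- paste(v[(o + 1):(o + 3)], collapse = "")
        if (oracle_translate(cand) == "*") next
        syn <- oracle_translate(cand) == oracle_translate(old)
        if ((class == "synonymous") == syn) {
          v[o + pos] <- b; done <- c(done, cod); hit <- TRUE; break
        }
      }
      if (hit) break
    }
  }
  if (length(done) < k) stop("could not plant ", k, " changes")
  list(cds = paste(v, collapse = ""), codons = done)
}

## random point-mutated copy of a nucleotide string
mutate_string <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1)
  paste(v, collapse = "")
}
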