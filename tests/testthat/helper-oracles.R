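# Independent oracles, deliberately implemented via different routes than the
# package (C++ dynamic programming / brute-force scans), compiled once per run.

# Semi-global ("fit") edit distance: the read aligned end-to-end, the amplicon
# with free end gaps. Independent of the Biostrings alignment route used by
# the package.
oracle_fit_distance <- local({
  fn <- NULL
  function(read, amplicon) {
    if (is.null(fn)) {
      fn <<- Rcpp::cppFunction("
        int fitdist(std::string r, std::string a) {
          int n = r.size(), m = a.size();
          std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
          // free leading gaps in the amplicon: row 0 cost 0
          for (int i = 1; i <= n; ++i) {
            cur[0] = i;  // read bases consumed against nothing: gap each
            for (int j = 1; j <= m; ++j) {
              int sub = prev[j - 1] + (r[i - 1] == a[j - 1] ? 0 : 1);
              int del = prev[j] + 1;   // gap in amplicon row
              int ins = cur[j - 1] + 1; // gap in read row
              cur[j] = std::min(sub, std::min(del, ins));
            }
            std::swap(prev, cur);
          }
          int best = prev[0];
          for (int j = 1; j <= m; ++j) best = std::min(best, prev[j]);
          return best;  // free trailing amplicon gaps: min over last row
        }")
    }
    fn(as.character(read), as.character(amplicon))
  }
})

# Exhaustive per-read assignment oracle: minimal fit distance over all loci
# and both orientations, ties collected; mirrors the documented decision rule
# but computes every distance with the C++ DP.
oracle_assign <- function(read, amplicons, margin = 0L, max_distance = 0.05) {
  r <- as.character(read)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  d_f <- vapply(amplicons, function(a) oracle_fit_distance(r, a), integer(1))
  d_r <- vapply(amplicons, function(a) oracle_fit_distance(rc, a), integer(1))
  dv <- if (min(d_r) < min(d_f)) d_r else d_f
  best <- min(dv)
  best_loci <- sort(names(dv)[dv <= best + margin])
  if (best > max_distance * nchar(amplicons[[which.min(dv)]]))
    list(status = "unassigned", loci = character(0), distance = best)
  else list(status = if (length(best_loci) == 1L) "unique" else "ambiguous",
            loci = best_loci, distance = best)
}

# Brute-force sliding-window primer matcher (no matchPattern).
oracle_primer_sites <- function(primer, sequence, max_mismatches) {
  p <- strsplit(primer, "", fixed = TRUE)[[1]]
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  k <- length(p); n <- length(s)
  if (k > n) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    if (sum(s[i:(i + k - 1L)] != p) <= max_mismatches)
      hits <- c(hits, i)
  }
  hits
}

# Brute-force interval finder replicating the documented pairing rule
# (every forward match paired with its nearest downstream reverse match),
# both strands.
oracle_match_primers <- function(sequence, primer_set) {
  revcomp <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  scan <- function(s, strand) {
    n <- nchar(s)
    fhits <- unlist(lapply(primer_set$forward, function(p) {
      h <- oracle_primer_sites(p, s, primer_set$max_mismatches)
      if (length(h)) lapply(h, function(x) c(start = x, len = nchar(p)))
    }), recursive = FALSE)
    rhits <- unlist(lapply(primer_set$reverse, function(p) {
      pr <- revcomp(p)
      h <- oracle_primer_sites(pr, s, primer_set$max_mismatches)
      if (length(h)) lapply(h, function(x) c(start = x, len = nchar(pr)))
    }), recursive = FALSE)
    if (is.null(fhits) || is.null(rhits)) return(NULL)
    out <- list()
    for (f in fhits) {
      cand <- Filter(function(r) r["start"] > f["start"] + f["len"] - 1L,
                     rhits)
      if (!length(cand)) next
      r <- cand[[which.min(vapply(cand, `[`, numeric(1), "start"))]]
      iv <- c(f["start"], r["start"] + r["len"] - 1L)
      if (strand == "-") iv <- c(n - iv[2] + 1L, n - iv[1] + 1L)
      out[[length(out) + 1L]] <- data.frame(start = iv[1], end = iv[2],
                                            strand = strand)
    }
    if (length(out)) do.call(rbind, out)
  }
  res <- rbind(scan(sequence, "+"), scan(revcomp(sequence), "-"))
  if (is.null(res)) return(res)
  res <- unique(res)
  res[order(res$start, res$end), , drop = FALSE]
}

# Permutation oracle for two-group comparisons: permutes group labels and
# recomputes the statistic; two-sided p with the +1 correction.
oracle_permutation_p <- function(x, y, statistic, n_perm = 10000L) {
  obs <- statistic(x, y)
  pool <- c(x, y)
  n <- length(x)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n)
    if (abs(statistic(pool[idx], pool[-idx])) >= abs(obs) - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1L) / (n_perm + 1L)
}
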