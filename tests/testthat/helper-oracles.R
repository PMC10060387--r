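# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: dense popcount loops, full sorts, exhaustive matching
# enumeration.

# Tanimoto by dense 0/1 vectors and explicit counting.
oracle_tanimoto <- function(bits_a, bits_b, nbits) {
  va <- integer(nbits); vb <- integer(nbits)
  va[bits_a] <- 1L; vb[bits_b] <- 1L
  inter <- 0L; un <- 0L
  for (i in seq_len(nbits)) {
    if (va[i] == 1L && vb[i] == 1L) inter <- inter + 1L
    if (va[i] == 1L || vb[i] == 1L) un <- un + 1L
  }
  if (un == 0L) 0 else inter / un
}

random_fingerprint <- function(nbits = 256, density = 0.1) {
  as_fingerprint(sample.int(nbits, max(1, round(density * nbits))),
                 nbits = nbits)
}

# Full-sort top-k oracle over a similarity vector with lexicographic
# tie-break on keys.
oracle_top_k <- function(sims, keys, k) {
  o <- order(-sims, keys)
  o[seq_len(min(k, length(o)))]
}

# Exhaustive optimal one-to-one matching over admissible peak pairs,
# maximising the summed intensity product. Only usable for tiny spectra.
oracle_assignment_score <- function(sa, sb, tolerance = 0.05,
                                    shift = FALSE) {
  d <- outer(sa$mz, sb$mz, "-")
  adm <- abs(d) <= tolerance
  if (shift) {
    delta <- sa$precursor_mz - sb$precursor_mz
    adm <- adm | (abs(d - delta) <= tolerance)
  }
  pairs <- which(adm, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0)
  prods <- sa$intensity[pairs[, 1]] * sb$intensity[pairs[, 2]]
  best <- 0
  recurse <- function(idx, used_a, used_b, acc) {
    if (idx > nrow(pairs)) {
      best <<- max(best, acc)
      return()
    }
    a <- pairs[idx, 1]; b <- pairs[idx, 2]
    if (!used_a[a] && !used_b[b]) {
      used_a[a] <- TRUE; used_b[b] <- TRUE
      recurse(idx + 1, used_a, used_b, acc + prods[idx])
      used_a[a] <- FALSE; used_b[b] <- FALSE
    }
    recurse(idx + 1, used_a, used_b, acc)
  }
  recurse(1, logical(length(sa$mz)), logical(length(sb$mz)), 0)
  best / (sqrt(sum(sa$intensity^2)) * sqrt(sum(sb$intensity^2)))
}

# Random spectrum with well-separated peaks (no two peaks of a spectrum
# closer than `min_gap`).
random_toy_spectrum <- function(id, n_peaks, precursor, lo = 50, hi = 450,
                                min_gap = 1.5) {
  mz <- numeric(0)
  while (length(mz) < n_peaks) {
    cand <- runif(1, lo, hi)
    if (!length(mz) || min(abs(mz - cand)) > min_gap) mz <- c(mz, cand)
  }
  s <- ms2_spectrum(id, sort(mz), runif(n_peaks, 0.1, 1),
                    precursor_mz = precursor, ionmode = "positive")
  attr(s, "cleaned") <- TRUE
  s
}

# Conflict-free toy pair for the matching oracles: peaks of `sb` are kept
# copies (small jitter), precursor-shifted copies, or fresh peaks, with
# rejection sampling so that every peak has at most one admissible
# partner under both direct and shifted matching.
conflict_free_toy_pair <- function(seed, tolerance = 0.05) {
  set.seed(seed)
  delta <- runif(1, 5, 30)
  na <- sample(3:6, 1)
  sa <- random_toy_spectrum("a", na, precursor = runif(1, 200, 500))
  ok_sep <- function(v, cand, gap) !length(v) || min(abs(v - cand)) > gap
  mzb <- numeric(0)
  for (i in seq_len(na)) {
    kind <- sample(c("keep", "shift", "drop"), 1,
                   prob = c(0.4, 0.4, 0.2))
    cand <- switch(kind, keep = sa$mz[i] + runif(1, -0.02, 0.02),
                   shift = sa$mz[i] - delta + runif(1, -0.02, 0.02),
                   drop = NA_real_)
    if (is.na(cand)) next
    # accept only if the peak has at most one admissible partner in sa,
    # counting both direct and precursor-shifted adjacency (4x tolerance
    # safety margin keeps the toy conflict-free)
    n_partners <- sum(abs(sa$mz - cand) < 4 * tolerance) +
      sum(abs(sa$mz - cand - delta) < 4 * tolerance)
    if (ok_sep(mzb, cand, 1.0) && n_partners <= 1) {
      mzb <- c(mzb, cand)
    }
  }
  nextra <- sample(0:2, 1)
  for (j in seq_len(nextra)) {
    for (try in 1:20) {
      cand <- runif(1, 50, 450)
      if (ok_sep(mzb, cand, 1.0) &&
          all(abs(sa$mz - cand) > 4 * tolerance) &&
          all(abs(sa$mz - cand - delta) > 4 * tolerance)) {
        mzb <- c(mzb, cand); break
      }
    }
  }
  if (length(mzb) < 1) mzb <- sa$mz[1] + 0.01
  o <- order(mzb)
  sb <- ms2_spectrum("b", mzb[o], runif(length(mzb), 0.1, 1),
                     precursor_mz = sa$precursor_mz - delta,
                     ionmode = "positive")
  attr(sb, "cleaned") <- TRUE
  list(sa = sa, sb = sb, delta = delta)
}
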