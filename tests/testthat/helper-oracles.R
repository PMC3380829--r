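# Brute-force oracles used to validate the compiled kernels.

# DP feasibility oracle for the bounded-difference matcher, over states
# (ref bases consumed j, difference events e, indel bases g) per query
# prefix i.  Mismatch = 1 event; a run of L inserted/deleted bases = 1 event
# and L indel bases (total <= maxB).  Insertions (extra reference bases)
# internal only; deletions (skipped query bases) anywhere.  Query matches
# globally, reference locally.
oracle_feasible <- function(q, r, maxd = 2L, maxB = 4L) {
  qv <- utf8ToInt(q)
  rv <- utf8ToInt(r)
  n <- length(qv)
  m <- length(rv)
  bases <- utf8ToInt("ACGT")
  dims <- c(m + 1, maxd + 1, maxB + 1)
  F <- vector("list", n + 1)
  for (i in 0:n) F[[i + 1]] <- array(FALSE, dims)
  F[[1]][, 1, 1] <- TRUE
  for (i in 0:n) {
    cur <- F[[i + 1]]
    if (i > 0 && i < n) {
      for (pass in seq_len(maxd)) {
        upd <- FALSE
        for (e in 0:(maxd - 1)) for (g in 0:(maxB - 1)) {
          src <- cur[, e + 1, g + 1]
          if (!any(src)) next
          for (L in 1:(maxB - g)) {
            js <- which(src) - 1L
            js <- js[js + L <= m]
            if (length(js)) {
              tgt <- cur[js + L + 1, e + 2, g + L + 1]
              if (any(!tgt)) {
                cur[js + L + 1, e + 2, g + L + 1] <- TRUE
                upd <- TRUE
              }
            }
          }
        }
        if (!upd) break
      }
      F[[i + 1]] <- cur
    }
    if (i == n) break
    for (e in 0:(maxd - 1)) for (g in 0:(maxB - 1)) {
      src <- cur[, e + 1, g + 1]
      if (!any(src)) next
      for (L in 1:(maxB - g)) {
        if (i + L > n) break
        F[[i + L + 1]][src, e + 2, g + L + 1] <- TRUE
      }
    }
    nxt <- F[[i + 2]]
    qc <- qv[i + 1]
    okbase <- qc %in% bases
    for (e in 0:maxd) for (g in 0:maxB) {
      src <- which(cur[, e + 1, g + 1]) - 1L
      src <- src[src < m]
      if (!length(src)) next
      mt <- okbase & (rv[src + 1] == qc)
      if (any(mt)) nxt[src[mt] + 2, e + 1, g + 1] <- TRUE
      if (e < maxd && any(!mt)) nxt[src[!mt] + 2, e + 2, g + 1] <- TRUE
    }
    F[[i + 2]] <- nxt
  }
  any(F[[n + 1]])
}

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Which references (by index) does `q` match on either strand?
oracle_match_set <- function(q, refs, maxd = 2L, maxB = 4L) {
  qr <- oracle_revcomp(q)
  which(vapply(refs, function(r) {
    oracle_feasible(q, r, maxd, maxB) || oracle_feasible(qr, r, maxd, maxB)
  }, TRUE))
}

# Brute-force shift identity: fraction of equal bases between the sequence
# and its copy shifted by s (N never matches).
oracle_shift_identity <- function(seq, s) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  a <- v[1:(n - s)]
  b <- v[(s + 1):n]
  mean(a == b & a != "N")
}

random_dna_str <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# Random 31-nt query: usually a mutated reference substring (substitutions,
# deletions, insertions), sometimes pure noise.
make_query <- function(refs) {
  if (runif(1) < 0.8) {
    r <- refs[[sample(length(refs), 1)]]
    st <- sample(100 - 35, 1)
    v <- strsplit(substr(r, st, st + 30 + sample(0:4, 1)), "")[[1]]
    for (o in seq_len(sample(0:3, 1))) {
      op <- sample(3, 1)
      if (op == 1) {
        p <- sample(length(v), 1)
        v[p] <- sample(c("A", "C", "G", "T"), 1)
      } else if (op == 2 && length(v) > 34) {
        L <- sample(1:3, 1)
        p <- sample(length(v) - L, 1)
        v <- v[-(p:(p + L - 1))]
      } else if (length(v) > 2) {
        L <- sample(1:3, 1)
        p <- sample(2:(length(v) - 1), 1)
        v <- append(v, sample(c("A", "C", "G", "T"), L, TRUE), after = p)
      }
    }
    if (length(v) > 31) v <- v[1:31]
    paste(v, collapse = "")
  } else {
    random_dna_str(31)
  }
}
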