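# Internal helpers shared across modules.

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, seed == floor(seed),
              abs(seed) < 2^31)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Reverse-complement character vector of DNA strings.
str_revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of length n with expected AT fraction `at` (iid bases).
random_dna <- function(n, at = 0.5) {
  if (n <= 0) return("")
  p <- c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Consensus of length n with EXACT AT base count round(n * at); the base
# identities and positions are random.  Exact counts keep the realized AT
# content within 0.5/n of the target, satisfying the generator contract even
# for short monomers.
consensus_dna <- function(n, at) {
  n_at <- round(n * at)
  bases <- c(sample(c("A", "T"), n_at, replace = TRUE),
             sample(c("C", "G"), n - n_at, replace = TRUE))
  paste(sample(bases), collapse = "")
}

# Independent per-base substitutions with probability `divergence`; mutated
# bases become one of the three other bases uniformly.
mutate_dna <- function(x, divergence) {
  if (divergence <= 0) return(x)
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < divergence)
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T",  "A", "G", "T",
                    "A", "C", "T",  "A", "C", "G"),
                  nrow = 3,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    pick <- sample.int(3, length(hit), replace = TRUE)
    v[hit] <- alt[cbind(pick, match(v[hit], colnames(alt)))]
  }
  paste(v, collapse = "")
}

# Phred+33 encoding helpers.
phred_to_string <- function(q) intToUtf8(pmin(pmax(q, 0L), 60L) + 33L)
string_to_phred <- function(s) utf8ToInt(s) - 33L

# Count bases with quality below `threshold` in Phred+33 quality strings.
count_low_quality <- function(quality, threshold) {
  if (threshold <= 0) return(integer(length(quality)))
  hi <- 33L + as.integer(threshold) - 1L
  cls <- sprintf("[\\x21-\\x%02X]", hi)
  nchar(quality) - nchar(gsub(cls, "", quality, perl = TRUE))
}

# Half-up rounding (Table-style reporting), as opposed to base R's
# round-half-even.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  out <- floor(x * m + 0.5) / m
  out[is.infinite(x) | is.na(x)] <- x[is.infinite(x) | is.na(x)]
  out
}

# Resolve a reads argument that may be a tibble or a file path.
resolve_reads <- function(x, need_quality = FALSE, arg = "reads") {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- if (need_quality) read_fastq(x) else read_sequences(x)
  }
  if (is.character(x)) {
    x <- tibble::tibble(
      read_id = if (!is.null(names(x))) names(x) else
        sprintf("read_%06d", seq_along(x)),
      sequence = unname(x)
    )
  }
  if (!is.data.frame(x) || !"sequence" %in% names(x)) {
    stop(sprintf("`%s` must be a tibble with a `sequence` column, ", arg),
         "a named character vector, or a readable file path", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"read_id" %in% names(x)) {
    x$read_id <- sprintf("read_%06d", seq_len(nrow(x)))
  }
  if (need_quality && !"quality" %in% names(x)) {
    stop(sprintf("`%s` must carry a `quality` column (FASTQ input required)",
                 arg), call. = FALSE)
  }
  x
}
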