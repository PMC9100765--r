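DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' A PWM holds per-position base frequencies over A, C, G, T together with
#' the derived per-position information vector and the contiguous run of
#' (at most) five positions with the largest summed information, used as
#' the motif core during scanning.
#'
#' @param name Matrix / transcription factor identifier.
#' @param freq Numeric matrix, one row per motif position, columns A, C, G,
#'   T; every row must sum to 1 (tolerance 1e-9).
#' @return An object of class `pwm` with elements `name`, `length`, `freq`,
#'   `info` and `core_positions`.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 0, 0,
#'               0.25, 0.25, 0.25, 0.25), ncol = 4, byrow = TRUE)
#' p <- pwm("toy", m)
#' p$info  # ln 4 at the fixed position, 0 at the uniform one
pwm <- function(name, freq) {
  freq <- as.matrix(freq)
  if (ncol(freq) != 4L) stop("PWM frequency matrix must have 4 columns (A,C,G,T)")
  if (any(freq < -1e-12)) stop("PWM frequencies must be nonnegative")
  freq[freq < 0] <- 0
  rs <- rowSums(freq)
  if (any(abs(rs - 1) > 1e-9)) stop("PWM rows must each sum to 1")
  colnames(freq) <- DNA_BASES
  rownames(freq) <- NULL
  info <- information_vector(freq)
  obj <- structure(
    list(name = as.character(name), length = nrow(freq), freq = freq,
         info = info, core_positions = core_positions(info)),
    class = "pwm")
  obj$.aux <- pwm_scoring_aux(obj)
  obj
}

#' Per-position information vector of a PWM
#'
#' I(i) = sum over bases b of f(i,b) * ln(4 f(i,b)), with 0 * ln 0 taken as
#' 0. A uniform position has I = 0; a single-base position has I = ln 4.
#'
#' @param pwm A `pwm` object or a frequency matrix (rows = positions,
#'   columns = A, C, G, T).
#' @return Numeric vector of length equal to the motif length.
#' @export
information_vector <- function(pwm) {
  freq <- if (inherits(pwm, "pwm")) pwm$freq else as.matrix(pwm)
  term <- freq * log(4 * freq)
  term[freq == 0] <- 0
  pmax(rowSums(term), 0)
}

# Contiguous run of min(5, L) positions maximizing summed information.
core_positions <- function(info) {
  L <- length(info)
  w <- min(5L, L)
  sums <- vapply(seq_len(L - w + 1L), function(s) sum(info[s:(s + w - 1L)]), 0)
  s <- which.max(sums)  # first maximum: deterministic
  s:(s + w - 1L)
}

# Precomputed quantities for window scoring.
pwm_scoring_aux <- function(p) {
  w <- p$info * p$freq                       # L x 4, I(i) * f(i,b)
  fmin <- apply(p$freq, 1L, min)
  fmax <- apply(p$freq, 1L, max)
  core <- p$core_positions
  list(
    wmat = t(w),                             # 4 x L for column-major lookup
    min_sum = sum(p$info * fmin),
    max_sum = sum(p$info * fmax),
    core_min = sum(p$info[core] * fmin[core]),
    core_max = sum(p$info[core] * fmax[core]))
}

#' Is a PWM scorable?
#'
#' A matrix whose positions are all uniform has identical minimum and
#' maximum attainable scores; the normalized similarity score is then
#' undefined and the matrix is excluded from scanning.
#'
#' @param pwm A `pwm` object.
#' @return Logical scalar.
#' @export
is_scorable <- function(pwm) {
  aux <- pwm$.aux %||% pwm_scoring_aux(pwm)
  (aux$max_sum - aux$min_sum) > 1e-12
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode a DNA string as integer codes
#'
#' A=1, C=2, G=3, T=4; any other character (including N) becomes NA and
#' windows covering it are not scored.
#'
#' @param seq Single DNA string.
#' @return Integer vector.
#' @keywords internal
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], DNA_BASES)
}

# Score every offset of `codes` (plus strand only). Returns a matrix with
# columns offset (0-based), mss, core; rows with NA scores are kept as NA.
score_offsets <- function(codes, pwm) {
  L <- pwm$length
  n <- length(codes)
  if (n < L) return(matrix(numeric(0), ncol = 3L,
                           dimnames = list(NULL, c("offset", "mss", "core"))))
  aux <- pwm$.aux %||% pwm_scoring_aux(pwm)
  offs <- 0:(n - L)
  idx <- outer(offs, seq_len(L), `+`)          # (n-L+1) x L positions (1-based)
  basemat <- matrix(codes[idx], nrow = length(offs))
  flat <- basemat + (col(basemat) - 1L) * 4L   # index into 4 x L wmat
  contrib <- matrix(aux$wmat[flat], nrow = nrow(basemat))
  cur <- rowSums(contrib)
  core_cols <- pwm$core_positions
  cur_core <- rowSums(contrib[, core_cols, drop = FALSE])
  denom <- aux$max_sum - aux$min_sum
  denom_core <- aux$core_max - aux$core_min
  mss <- (cur - aux$min_sum) / denom
  core <- if (denom_core > 1e-12) (cur_core - aux$core_min) / denom_core else
    rep(1, length(cur_core))
  cbind(offset = offs,
        mss = pmin(pmax(mss, 0), 1),
        core = pmin(pmax(core, 0), 1))
}

#' MATCH-style matrix similarity score of a single window
#'
#' Scores a sequence window of exactly the motif length:
#' `mss = (Current - Min) / (Max - Min)` where
#' `Current = sum_i I(i) f(i, s_i)` and Min / Max use the per-position
#' minimum / maximum frequency. The core score applies the same formula
#' restricted to the motif's five most informative consecutive positions.
#'
#' @param pwm A `pwm` object.
#' @param window_seq String of length `pwm$length` over A, C, G, T.
#' @return Named numeric vector `c(mss=, core=)`, both in \[0, 1\].
#' @export
matrix_similarity_score <- function(pwm, window_seq) {
  codes <- encode_dna(window_seq)
  if (length(codes) != pwm$length)
    stop("window length must equal PWM length")
  if (anyNA(codes)) stop("window contains non-ACGT characters")
  if (!is_scorable(pwm))
    stop(sprintf("PWM '%s' is unscorable (all positions uniform)", pwm$name))
  sc <- score_offsets(codes, pwm)
  c(mss = unname(sc[1L, "mss"]), core = unname(sc[1L, "core"]))
}

#' Scan a sequence with one PWM on both strands
#'
#' Slides the motif over every offset of `seq` on the plus strand and over
#' its reverse complement for the minus strand, and reports hits whose core
#' score and matrix similarity score both reach their cutoffs. Minus-strand
#' offsets refer to the start of the hit span in the input sequence.
#'
#' @param seq DNA string.
#' @param pwm A `pwm` object.
#' @param mss_cutoff,core_cutoff Score cutoffs in \[0, 1\].
#' @return data.frame with columns `pwm`, `strand`, `offset` (0-based start
#'   within `seq`), `mss`, `core`; zero rows if no hit or if the sequence is
#'   shorter than the motif.
#' @export
scan_sequence <- function(seq, pwm, mss_cutoff = 0.95, core_cutoff = 0.90) {
  stopifnot(mss_cutoff >= 0, mss_cutoff <= 1, core_cutoff >= 0, core_cutoff <= 1)
  if (!is_scorable(pwm)) {
    warning(sprintf("PWM '%s' is unscorable and was excluded from scanning",
                    pwm$name))
    return(empty_hits())
  }
  codes <- if (is.integer(seq)) seq else encode_dna(seq)
  scan_codes(codes, pwm, mss_cutoff, core_cutoff)
}

empty_hits <- function() {
  data.frame(pwm = character(0), strand = character(0), offset = integer(0),
              mss = numeric(0), core = numeric(0), stringsAsFactors = FALSE)
}

# Internal scanning on pre-encoded codes (no scorability warning).
scan_codes <- function(codes, pwm, mss_cutoff, core_cutoff) {
  n <- length(codes)
  L <- pwm$length
  if (n < L) return(empty_hits())
  fwd <- score_offsets(codes, pwm)
  rc <- rev(5L - codes)                      # reverse complement codes
  rev_sc <- score_offsets(rc, pwm)
  out <- list()
  keep_f <- which(!is.na(fwd[, "mss"]) & fwd[, "mss"] >= mss_cutoff &
                    fwd[, "core"] >= core_cutoff)
  if (length(keep_f))
    out[[1L]] <- data.frame(pwm = pwm$name, strand = "+",
                            offset = as.integer(fwd[keep_f, "offset"]),
                            mss = fwd[keep_f, "mss"], core = fwd[keep_f, "core"],
                            stringsAsFactors = FALSE)
  keep_r <- which(!is.na(rev_sc[, "mss"]) & rev_sc[, "mss"] >= mss_cutoff &
                    rev_sc[, "core"] >= core_cutoff)
  if (length(keep_r))
    out[[length(out) + 1L]] <-
      data.frame(pwm = pwm$name, strand = "-",
                 offset = as.integer((n - L) - rev_sc[keep_r, "offset"]),
                 mss = rev_sc[keep_r, "mss"], core = rev_sc[keep_r, "core"],
                 stringsAsFactors = FALSE)
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  res[order(res$offset, res$strand), , drop = FALSE]
}

# Best (maximum) mss over all offsets and strands, ignoring cutoffs.
best_mss <- function(codes, pwm) {
  fwd <- score_offsets(codes, pwm)[, "mss"]
  rev_sc <- score_offsets(rev(5L - codes), pwm)[, "mss"]
  vals <- c(fwd, rev_sc)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) NA_real_ else max(vals)
}

#' Print method for PWM objects
#' @param x A `pwm` object.
#' @param ... Ignored.
#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, total information %.3f nats, core %d-%d\n",
              x$name, x$length, sum(x$info),
              min(x$core_positions), max(x$core_positions)))
  invisible(x)
}

consensus_string <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 1L, which.max)], collapse = "")
}

#' Write PWMs to a TRANSFAC-style flat file
#'
#' Emits ID / BF / P0 blocks with per-position A C G T values (scaled to
#' counts out of 100) followed by the consensus letter, `XX` and `//`
#' terminators.
#'
#' @param pwms List of `pwm` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(sprintf("ID  %s", p$name), "BF  synthetic"), con)
    writeLines(sprintf("P0      %s", paste(sprintf("%8s", DNA_BASES), collapse = " ")), con)
    cons <- strsplit(consensus_string(p), "")[[1L]]
    for (i in seq_len(p$length)) {
      writeLines(sprintf("%02d      %s  %s", i,
                         paste(sprintf("%8.4f", 100 * p$freq[i, ]), collapse = " "),
                         cons[i]), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read PWMs from a TRANSFAC-style flat file
#'
#' Parses ID / P0 blocks; numbered rows carry A C G T counts which are
#' normalized to frequencies on load.
#'
#' @param path File written by [write_transfac()] or in compatible format.
#' @return List of `pwm` objects, named by matrix identifier.
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  pwms <- list()
  name <- NULL
  rows <- list()
  flush_block <- function() {
    if (is.null(name)) return()
    if (!length(rows))
      stop(sprintf("%s: matrix '%s' has no frequency rows", path, name))
    freq <- do.call(rbind, rows)
    freq <- freq / rowSums(freq)
    pwms[[name]] <<- pwm(name, freq)
    name <<- NULL
    rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "XX") || startsWith(ln, "BF") ||
        startsWith(ln, "P0")) next
    if (startsWith(ln, "//")) { flush_block(); next }
    if (startsWith(ln, "ID")) {
      flush_block()
      name <- trimws(sub("^ID\\s+", "", ln))
      next
    }
    if (grepl("^[0-9]+\\s", ln)) {
      if (is.null(name))
        stop(sprintf("%s:%d: frequency row outside of an ID block", path, i))
      parts <- strsplit(ln, "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(parts[2:5]))
      if (anyNA(vals))
        stop(sprintf("%s:%d: malformed frequency row", path, i))
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush_block()
  pwms
}

#' Generate a library of synthetic PWMs
#'
#' Draws `n_pwms` motifs of lengths sampled from `length_range`. Most
#' positions are informative (one dominant base at frequency 0.8-0.97); the
#' central position is forced to be highly informative so a consensus site
#' is plantable and a single central mismatch is score-relevant.
#'
#' @param n_pwms Number of motifs (>= 1).
#' @param length_range Integer vector `c(min, max)` of motif lengths, min >= 6.
#' @param seed Integer seed; the library is a pure function of the arguments.
#' @return Named list of `pwm` objects with unique names `TF001`, `TF002`, ...
#' @export
generate_pwm_library <- function(n_pwms, length_range = c(8, 12), seed = 1) {
  if (n_pwms < 1) stop("n_pwms must be >= 1")
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stop("degenerate length_range: min must not exceed max")
  if (length_range[1] < 6) stop("motif lengths must be >= 6")
  set.seed(seed)
  out <- vector("list", n_pwms)
  names(out) <- sprintf("TF%03d", seq_len(n_pwms))
  for (k in seq_len(n_pwms)) {
    L <- sample(seq(length_range[1], length_range[2]), 1L)
    freq <- matrix(0, L, 4L)
    anchor <- as.integer(ceiling(L / 2))
    for (i in seq_len(L)) {
      informative <- (i == anchor) || (stats::runif(1) < 0.7)
      if (informative) {
        dom <- sample.int(4L, 1L)
        fd <- if (i == anchor) stats::runif(1, 0.90, 0.97) else stats::runif(1, 0.80, 0.97)
        rest <- stats::runif(3)
        rest <- rest / sum(rest) * (1 - fd)
        freq[i, dom] <- fd
        freq[i, -dom] <- rest
      } else {
        g <- stats::rgamma(4L, shape = 5)
        freq[i, ] <- g / sum(g)
      }
    }
    out[[k]] <- pwm(names(out)[k], freq)
  }
  out
}
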