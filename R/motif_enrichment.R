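#' Construct a position weight matrix
#'
#' Builds the probability and log2-odds representation of a motif from a
#' count (or probability) matrix over A/C/G/T, with a pseudocount and a
#' background distribution. Scores are in bits: `log2(p / bg)` summed over
#' positions.
#'
#' @param counts 4 x W numeric matrix, rows named A, C, G, T.
#' @param pseudocount Added to every cell before normalization (default
#'   0.25, split evenly across the column total).
#' @param background Background base frequencies (default uniform 0.25).
#' @param name Motif identifier.
#' @return A `PWM` object (list with `name`, `width`, `prob`, `background`,
#'   `log_odds`, `max_score`).
#' @export
pwm <- function(counts, pseudocount = 0.25,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM matrix must have 4 rows (A,C,G,T)")
  rownames(counts) <- c("A", "C", "G", "T")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  background <- background / sum(background)
  prob <- apply(counts + pseudocount, 2, function(col) col / sum(col))
  lo <- log2(prob / background)
  structure(list(name = name, width = ncol(prob), prob = prob,
                 background = background, log_odds = lo,
                 max_score = sum(apply(lo, 2, max))),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM", x$name, "- width", x$width,
      sprintf("- max score %.2f bits\n", x$max_score))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x A `PWM`.
#' @return Character string of length `width`.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$prob)[apply(x$prob, 2, which.max)], collapse = "")
}

#' Read motifs from a JASPAR-format text file
#'
#' Parses entries of the form `>ID name` followed by four lines
#' `A [ 1 2 3 ]` ... `T [ ... ]` (brackets optional).
#'
#' @param path Path to the JASPAR text file.
#' @param pseudocount,background Passed to [pwm()].
#' @return Named list of `PWM` objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.25,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!file.exists(path)) stop("PWM file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no JASPAR records (no '>' header) in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    name <- strsplit(hdr, "\\s+")[[1]][1]
    last <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    body <- lines[(starts[i] + 1):last]
    if (length(body) < 4) stop("JASPAR record ", name, " has fewer than 4 rows")
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      base <- toupper(parts[1])
      vals <- suppressWarnings(as.numeric(parts[-1]))
      if (!base %in% c("A", "C", "G", "T") || anyNA(vals))
        stop("malformed JASPAR row in record ", name, ": ", l)
      list(base = base, vals = vals)
    })
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(m) <- vapply(rows, `[[`, "", "base")
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    out[[name]] <- pwm(m, pseudocount = pseudocount, background = background,
                       name = name)
  }
  out
}

# integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else NA
.encode_dna <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  match(v, c("A", "C", "G", "T"))
}

.revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# log-odds score of every window of width W in an encoded sequence;
# windows containing N (NA codes) score NA
.window_scores <- function(code, lo) {
  W <- ncol(lo)
  L <- length(code)
  if (L < W) return(numeric(0))
  n_win <- L - W + 1
  sc <- numeric(n_win)
  for (j in seq_len(W)) sc <- sc + lo[cbind(code[j:(j + n_win - 1)], j)]
  sc
}

#' Scan sequences with a PWM
#'
#' Scores every window on both strands with the PWM's log2-odds matrix and
#' reports all windows at or above the threshold. Windows containing `N`
#' are skipped; sequences shorter than the motif yield no hits. Offsets are
#' 0-based positions on the forward strand of the window's first base.
#'
#' @param sequences Named character vector of DNA sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param pwm A `PWM`.
#' @param threshold Minimum score in bits; default 80% of the PWM's maximum
#'   achievable score.
#' @return data.frame with `sequence_id`, `offset`, `strand`, `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold = 0.8 * pwm$max_score) {
  if (inherits(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq_", seq_along(sequences))
  W <- pwm$width
  hits <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    L <- nchar(s)
    rows <- list()
    fwd <- .window_scores(.encode_dna(s), pwm$log_odds)
    ok <- which(!is.na(fwd) & fwd >= threshold)
    if (length(ok))
      rows[["+"]] <- data.frame(sequence_id = names(sequences)[i],
                                offset = ok - 1L, strand = "+",
                                score = fwd[ok], stringsAsFactors = FALSE)
    rev <- .window_scores(.encode_dna(.revcomp(s)), pwm$log_odds)
    ok <- which(!is.na(rev) & rev >= threshold)
    if (length(ok))
      # offset of a reverse-strand window, reported on the forward strand
      rows[["-"]] <- data.frame(sequence_id = names(sequences)[i],
                                offset = L - W + 1L - ok, strand = "-",
                                score = rev[ok], stringsAsFactors = FALSE)
    hits[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(sequence_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: treats the sequence as an Eulerian walk on the
#' dinucleotide multigraph and samples a random walk with the same edge
#' multiset, so mono- and dinucleotide counts are preserved exactly. Uses
#' R's RNG (seed with `set.seed` for reproducibility).
#'
#' @param seq A single DNA string.
#' @return A shuffled string with identical dinucleotide composition.
#' @export
dinucleotide_shuffle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n <= 3) return(seq)
  verts <- unique(chars)
  if (length(verts) == 1) return(seq)
  edges <- lapply(setNames(verts, verts),
                  function(v) chars[which(chars[-n] == v) + 1L])
  first <- chars[1]; last <- chars[n]
  # choose a random "last edge" per non-terminal vertex forming a tree into
  # `last` (rejection sampling; alphabet is tiny so this converges fast)
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0) NA_character_
      else sample(edges[[v]], 1)
    }, "")
    ok <- TRUE
    for (v in verts) {
      if (v == last || length(edges[[v]]) == 0) next
      cur <- v; steps <- 0
      while (cur != last && steps <= length(verts)) {
        cur <- last_edge[[cur]]
        steps <- steps + 1
        if (is.na(cur)) break
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  shuffled <- lapply(setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (v == last || length(e) == 0) return(sample(e))
    le <- last_edge[[v]]
    e <- e[-match(le, e)]
    c(sample(e), le)
  })
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Motif enrichment of peak sequences over a background
#'
#' Compares the fraction of peak sequences containing at least one PWM hit
#' with the same fraction in a background set (by default, a per-sequence
#' dinucleotide shuffle of the peaks, size-matched by construction), with a
#' two-sided Fisher exact test on the 2x2 hit/no-hit x peak/background
#' table. Fold enrichment is the ratio of the two fractions.
#'
#' @param peak_sequences Named character vector or `DNAStringSet`.
#' @param pwm A `PWM`.
#' @param threshold Score threshold in bits (default 80% of maximum).
#' @param background_sequences Optional explicit background; if `NULL`,
#'   dinucleotide-shuffled copies of the peak sequences are used.
#' @param seed Seed for the shuffle (default 1).
#' @return list with `fold`, `p`, `frac_peaks`, `frac_background`, `table`.
#' @export
enrichment_test <- function(peak_sequences, pwm,
                            threshold = 0.8 * pwm$max_score,
                            background_sequences = NULL, seed = 1) {
  if (inherits(peak_sequences, "DNAStringSet")) {
    nm <- names(peak_sequences)
    peak_sequences <- as.character(peak_sequences)
    names(peak_sequences) <- nm
  }
  if (length(peak_sequences) == 0) stop("no peak sequences")
  if (is.null(background_sequences)) {
    set.seed(seed)
    background_sequences <- vapply(peak_sequences, dinucleotide_shuffle, "")
    names(background_sequences) <- paste0("bg_", seq_along(background_sequences))
  } else if (inherits(background_sequences, "DNAStringSet")) {
    background_sequences <- as.character(background_sequences)
  }
  if (length(background_sequences) == 0) stop("empty background")
  hit_frac <- function(seqs) {
    h <- scan_pwm(seqs, pwm, threshold)
    length(unique(h$sequence_id)) / length(seqs)
  }
  if (is.null(names(peak_sequences)))
    names(peak_sequences) <- paste0("seq_", seq_along(peak_sequences))
  fp <- hit_frac(peak_sequences)
  fb <- hit_frac(background_sequences)
  np <- length(peak_sequences); nb <- length(background_sequences)
  tab <- matrix(c(round(fp * np), np - round(fp * np),
                  round(fb * nb), nb - round(fb * nb)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("peak", "background"), c("hit", "no_hit")))
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  fold <- if (fb == 0) {
    if (fp == 0) 1 else Inf
  } else fp / fb
  list(fold = fold, p = p, frac_peaks = fp, frac_background = fb, table = tab)
}

#' Read a FASTA file of peak-region sequences
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
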