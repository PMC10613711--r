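#' @useDynLib idrsuite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a protein sequence object
#'
#' A `protein_sequence` holds a stretch of one-letter amino-acid codes together
#' with the number of its first residue, so that regions extracted from a
#' larger construct (e.g. a transactivation domain spanning residues 280-631
#' of a full-length transcription factor) keep their native numbering.
#'
#' @param residues character string of one-letter codes (case-insensitive).
#' @param id sequence identifier.
#' @param first_residue_number number assigned to the first residue (1-based).
#' @return an object of class `protein_sequence`.
#' @export
protein_sequence <- function(residues, id = "seq", first_residue_number = 1L) {
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) < 1L) stop("sequence must contain at least one residue")
  bad <- setdiff(strsplit(residues, "")[[1]], AA_CODES)
  if (length(bad) > 0L) {
    stop("non-canonical residue code(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(
    list(id = as.character(id), residues = residues,
         first_residue_number = as.integer(first_residue_number)),
    class = "protein_sequence"
  )
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

#' @export
print.protein_sequence <- function(x, ...) {
  n <- length(x)
  cat(sprintf("protein_sequence '%s': %d residues (%d-%d)\n", x$id, n,
              x$first_residue_number, x$first_residue_number + n - 1L))
  res <- x$residues
  if (n > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(" ", res, "\n")
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' Read protein sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @param on_nonstandard what to do with residues outside the 20 canonical
#'   codes: `"error"` (default) or `"remove"`.
#' @return a list of [protein_sequence()] objects, `first_residue_number = 1`.
#' @export
read_fasta <- function(path, on_nonstandard = c("error", "remove")) {
  on_nonstandard <- match.arg(on_nonstandard)
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, seqonly = FALSE),
    error = function(e) stop("no records in FASTA file: ", path)
  )
  if (length(recs) == 0L) stop("no records in FASTA file: ", path)
  lapply(seq_along(recs), function(i) {
    s <- toupper(as.character(recs[[i]])[1])
    if (on_nonstandard == "remove") {
      s <- paste(intersect_keep(strsplit(s, "")[[1]], AA_CODES), collapse = "")
      if (nchar(s) == 0L) stop("record '", names(recs)[i],
                               "' empty after removing non-canonical codes")
    }
    protein_sequence(s, id = names(recs)[i])
  })
}

intersect_keep <- function(x, keep) x[x %in% keep]

#' Write sequences to a FASTA file
#'
#' @param seqs a `protein_sequence` or list of them.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    writeLines(strwrap(s$residues, width = 70), con)
  }
  invisible(path)
}

#' Extract a residue-numbered region from a sequence
#'
#' Bounds are inclusive and expressed in the sequence's own numbering, so
#' `extract_region(fullseq, 280, 631)` returns the 352-residue region and the
#' result remembers that it starts at residue 280.
#'
#' @param seq a [protein_sequence()].
#' @param start,end first and last residue numbers of the region.
#' @return a [protein_sequence()] with `first_residue_number = start`.
#' @export
extract_region <- function(seq, start, end) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (start > end) stop("start must be <= end")
  lo <- seq$first_residue_number
  hi <- lo + length(seq) - 1L
  if (start < lo || end > hi) {
    stop(sprintf("region %d-%d outside sequence range %d-%d", start, end, lo, hi))
  }
  i <- start - lo + 1L
  j <- end - lo + 1L
  protein_sequence(substr(seq$residues, i, j),
                   id = sprintf("%s_%d-%d", seq$id, start, end),
                   first_residue_number = start)
}

#' Five-group residue categorization scheme
#'
#' The default partitions the 20 canonical residues into cations (R, K),
#' anions (D, E), aromatic (F, Y, W), aliphatic (A, C, I, L, M, P, V) and
#' hydrophilic (G, N, S, H, Q, T). Note histidine is treated as hydrophilic
#' and uncharged. The five sets must partition the amino-acid alphabet.
#'
#' @param cation,anion,aromatic,aliphatic,hydrophilic character vectors of
#'   one-letter codes.
#' @return named character vector mapping residue code to category, class
#'   `category_scheme`.
#' @export
category_scheme <- function(cation = c("R", "K"),
                            anion = c("D", "E"),
                            aromatic = c("F", "Y", "W"),
                            aliphatic = c("A", "C", "I", "L", "M", "P", "V"),
                            hydrophilic = c("G", "N", "S", "H", "Q", "T")) {
  sets <- list(cation = cation, anion = anion, aromatic = aromatic,
               aliphatic = aliphatic, hydrophilic = hydrophilic)
  all_res <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_res) || !setequal(all_res, AA_CODES)) {
    stop("the five sets must partition the 20 canonical residue codes")
  }
  map <- rep(names(sets), vapply(sets, length, 1L))
  names(map) <- all_res
  structure(map[AA_CODES], class = "category_scheme")
}

CATEGORY_NAMES <- c("cation", "anion", "aromatic", "aliphatic", "hydrophilic")

#' Per-residue category assignment
#'
#' @param seq a [protein_sequence()].
#' @param scheme a [category_scheme()].
#' @return character vector of categories, one per residue, named by residue
#'   number.
#' @export
categorize <- function(seq, scheme = category_scheme()) {
  stopifnot(inherits(seq, "protein_sequence"))
  ch <- seq_chars(seq)
  if (!all(ch %in% names(scheme))) {
    stop("residue(s) not covered by scheme: ",
         paste(unique(setdiff(ch, names(scheme))), collapse = ", "))
  }
  out <- unname(scheme[ch])
  names(out) <- seq$first_residue_number + seq_along(ch) - 1L
  out
}

#' Category composition fractions of a sequence
#'
#' Returns the fraction of residues in each of the five categories plus the
#' combined charged+polar fraction (cation + anion + hydrophilic); for
#' Ser/Thr-rich, charge-depleted disordered regions this combined fraction is
#' large (about 0.9 for the transactivation domain studied here).
#'
#' @inheritParams categorize
#' @return named numeric vector: the five category fractions (summing to 1)
#'   and `charged_polar`.
#' @export
composition_fractions <- function(seq, scheme = category_scheme()) {
  cats <- categorize(seq, scheme)
  n <- length(cats)
  fr <- vapply(CATEGORY_NAMES, function(k) sum(cats == k) / n, 1.0)
  c(fr, charged_polar = unname(fr["cation"] + fr["anion"] + fr["hydrophilic"]))
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector over the 20 canonical codes.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Per-residue formal charge (R, K = +1; D, E = -1; H = 0)
#' @return named numeric vector over the 20 canonical codes.
#' @export
residue_charges <- function() {
  ch <- setNames(rep(0, 20), AA_CODES)
  ch[c("R", "K")] <- 1
  ch[c("D", "E")] <- -1
  ch
}

#' Sliding-window composition profiles
#'
#' Windowed mean hydropathy, mean net charge, and the fraction of residues in
#' the low-complexity polar set \{S, T, N, Q, G, P\} at each position. Windows
#' are truncated (shrink) at the termini rather than padded.
#'
#' @param seq a [protein_sequence()].
#' @param window odd window width (residues); must not exceed the sequence
#'   length.
#' @param scale hydropathy scale, a named numeric vector covering the 20
#'   canonical codes (default [kyte_doolittle()]).
#' @param bias_set residue codes counted by the compositional-bias track.
#' @return a data.frame of class `composition_profile` with columns
#'   `position`, `residue`, `category`, `hydropathy`, `charge`, `bias`;
#'   attributes `window` and `scale_name`.
#' @export
sliding_profiles <- function(seq, window = 9L, scale = kyte_doolittle(),
                             bias_set = c("S", "T", "N", "Q", "G", "P")) {
  stopifnot(inherits(seq, "protein_sequence"))
  n <- length(seq)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > n) stop("window larger than sequence")
  if (!all(AA_CODES %in% names(scale))) stop("scale must cover all 20 codes")
  ch <- seq_chars(seq)
  hyd <- unname(scale[ch])
  chg <- unname(residue_charges()[ch])
  bia <- as.numeric(ch %in% bias_set)
  half <- (window - 1L) %/% 2L
  wmean <- function(v) {
    vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      mean(v[lo:hi])
    }, 1.0)
  }
  out <- data.frame(
    position = seq$first_residue_number + seq_len(n) - 1L,
    residue = ch,
    category = unname(categorize(seq)),
    hydropathy = wmean(hyd),
    charge = wmean(chg),
    bias = wmean(bia),
    stringsAsFactors = FALSE
  )
  attr(out, "window") <- as.integer(window)
  attr(out, "scale_name") <- "kyte_doolittle"
  class(out) <- c("composition_profile", "data.frame")
  out
}

#' @export
plot.composition_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$position, x$hydropathy, type = "l", ylab = "hydropathy", xlab = "")
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$position, x$charge, type = "l", ylab = "net charge", xlab = "")
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$position, x$bias, type = "l", ylab = "S/T/N/Q/G/P bias",
                 xlab = "residue", ylim = c(0, 1))
  invisible(x)
}
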