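# Structural Alphabet container, the bundled M32K25 alphabet, letter-group
# annotation and Table-style report rendering.

#' Construct a Structural Alphabet
#'
#' A Structural Alphabet is an ordered, lettered set of representative
#' four-residue fragment conformations, each stored as an internal-angle
#' triple.  Canonical Cartesian coordinates (atom 1 at the origin, uniform
#' virtual bonds) are materialised once at construction and reused by the
#' encoders.
#'
#' @param angles k x 3 numeric matrix of (phi1, phi2, theta) in degrees.
#' @param letters character vector of k unique single characters (defaults to
#'   `A, B, C, ...`).
#' @param name alphabet name, conventionally `M<MinPts>K<size>`.
#' @param bond virtual C-alpha--C-alpha bond length in Angstrom.
#' @return Object of class `structural_alphabet`: `name`, `letters`, `angles`
#'   (rownames = letters), `bond`, `canonical` (list of 4 x 3 matrices).
#' @export
structural_alphabet <- function(angles, letters = NULL, name = "custom",
                                bond = 3.8) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 3L) stop("'angles' must be a k x 3 matrix")
  k <- nrow(angles)
  if (k < 1L) stop("an alphabet needs at least one fragment")
  if (is.null(letters)) letters <- default_letters(k)
  letters <- as.character(letters)
  if (length(letters) != k) stop("need one letter per fragment")
  if (anyDuplicated(letters)) stop("alphabet letters must be unique")
  if (any(nchar(letters) != 1L) || any(!grepl("[[:print:]]", letters)) ||
      any(grepl("[[:space:]-]", letters)))
    stop("letters must be single printable non-blank characters ('-' is reserved)")
  apply(angles, 1L, .check_angles)
  dimnames(angles) <- list(letters, c("phi1", "phi2", "theta"))
  canonical <- lapply(seq_len(k), function(i) build_fragment(angles[i, ], bond))
  names(canonical) <- letters
  structure(list(name = as.character(name), letters = letters, angles = angles,
                 bond = bond, canonical = canonical),
            class = "structural_alphabet")
}

# A..Z then a..z; alphabets beyond 52 letters are refused.
default_letters <- function(k) {
  pool <- c(LETTERS, letters)
  if (k > length(pool)) stop("too many fragments for single-character letters")
  pool[seq_len(k)]
}

#' @export
print.structural_alphabet <- function(x, ...) {
  cat(sprintf("<structural_alphabet> %s: %d letters, bond %.2f Angstrom\n",
              x$name, length(x$letters), x$bond))
  print(round(x$angles, 1))
  invisible(x)
}

#' @export
length.structural_alphabet <- function(x) length(x$letters)

#' The bundled M32K25 Structural Alphabet
#'
#' The 25-letter alphabet derived from density attractors of the fragment
#' angle space (MinPts = 32), bundled with the package at 0.1-degree
#' precision.  Letters are ordered by the position of their cluster
#' representative along the density-ordering (reachability) walk; A-I cover
#' extended conformations, J-R loops, S-X helical geometries and Y turns.
#'
#' @return A `structural_alphabet` of 25 letters.
#' @examples
#' m32k25()$angles["A", ]
#' @export
m32k25 <- function() {
  load_alphabet("M32K25")
}

#' Read an alphabet from JSON
#'
#' The JSON schema is the package's canonical alphabet exchange format:
#' `{"name": ..., "bond": ..., "fragments": [{"letter", "phi1", "phi2",
#' "theta"}, ...]}`.  The reserved name `"M32K25"` loads the bundled
#' alphabet.
#'
#' @param path file path, or `"M32K25"`.
#' @return A `structural_alphabet`.
#' @export
load_alphabet <- function(path) {
  if (identical(path, "M32K25"))
    path <- system.file("extdata", "m32k25.json", package = "safrag",
                        mustWork = TRUE)
  if (!file.exists(path)) stop("no such alphabet file: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$fragments) || is.null(js$name))
    stop("not an alphabet file: missing 'name' or 'fragments'")
  fr <- js$fragments
  angles <- cbind(fr$phi1, fr$phi2, fr$theta)
  structural_alphabet(angles, letters = fr$letter, name = js$name,
                      bond = if (is.null(js$bond)) 3.8 else js$bond)
}

#' Write an alphabet to JSON
#'
#' @param alphabet a `structural_alphabet`.
#' @param path output file.
#' @return `path`, invisibly.  `load_alphabet(save_alphabet(a, f))` restores
#'   `a` losslessly.
#' @export
save_alphabet <- function(alphabet, path) {
  stopifnot(inherits(alphabet, "structural_alphabet"))
  fragments <- data.frame(letter = alphabet$letters,
                          phi1 = alphabet$angles[, 1L],
                          phi2 = alphabet$angles[, 2L],
                          theta = alphabet$angles[, 3L],
                          row.names = NULL)
  jsonlite::write_json(list(name = alphabet$name, bond = alphabet$bond,
                            fragments = fragments),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# letter -> coarse class map of the bundled alphabet: seven reachability-plot
# areas collapsed to extended/loop/helix/turn.
.m32k25_groups <- function() {
  data.frame(
    letter = LETTERS[1:25],
    group = c(rep("A-I", 9), rep("J-L", 3), rep("M-N", 2), rep("O-R", 4),
              rep("S-W", 5), "X", "Y"),
    class = c(rep("E", 9), rep("L", 9), rep("H", 6), "T"),
    stringsAsFactors = FALSE)
}

#' Coarse structural class per M32K25 letter
#'
#' Maps letters of the bundled alphabet to the coarse class of the
#' reachability-plot area they belong to: `E` (extended, A-I), `L` (loop,
#' J-R), `H` (helical, S-X), `T` (turn, Y).  The mapping is reporting sugar
#' only -- letters are conformational states, not secondary-structure
#' assignments -- and is never used in any computation.
#'
#' @param letters character string (or vector of single letters) over A-Y.
#' @return Character string of the same length over `E/L/H/T`.
#' @examples
#' annotate_letters("AAPUY")
#' @export
annotate_letters <- function(letters) {
  if (length(letters) == 1L && nchar(letters) > 1L)
    letters <- strsplit(letters, "")[[1L]]
  map <- .m32k25_groups()
  idx <- match(letters, map$letter)
  if (anyNA(idx)) stop("unknown M32K25 letter(s): ",
                       paste(unique(letters[is.na(idx)]), collapse = ", "))
  paste(map$class[idx], collapse = "")
}

#' Render an alphabet-ranking table
#'
#' Formats the output of [rank_alphabets()] (name, size, median/IQD of local
#' and global fit, AIC in kbit) as TSV or markdown text.
#'
#' @param rank_table data.frame as returned by [rank_alphabets()].
#' @param format `"tsv"` or `"markdown"`.
#' @return Character vector of lines.
#' @export
report_ranking <- function(rank_table, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  cols <- c("name", "k", "local_median", "local_iqd",
            "global_median", "global_iqd", "aic_kbit")
  header <- c("alphabet", "k", "local/A", "IQD/A", "global/A", "IQD/A",
              "AIC/kbit")
  tab <- rank_table[, cols, drop = FALSE]
  fmt_row <- function(r)
    c(as.character(r[[1L]]), as.character(r[[2L]]),
      sprintf("%.3f", as.numeric(r[3:6])), sprintf("%.1f", as.numeric(r[[7L]])))
  rows <- if (nrow(tab)) lapply(seq_len(nrow(tab)), function(i) fmt_row(tab[i, ]))
          else list()
  if (format == "tsv") {
    c(paste(header, collapse = "\t"),
      vapply(rows, paste, "", collapse = "\t"))
  } else {
    c(paste0("| ", paste(header, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
      vapply(rows, function(r) paste0("| ", paste(r, collapse = " | "), " |"), ""))
  }
}
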