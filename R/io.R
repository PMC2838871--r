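# Structure and table I/O: C-alpha traces from (multi-model) PDB files,
# CA-only PDB writing, structure-string FASTA/TSV, reachability tables.
# PDB records are parsed by bio3d; this module only adds the C-alpha
# selection policy (altloc by occupancy, HETATM C-alpha such as MSE included,
# calcium ions excluded) and ensemble consistency checks.

#' Construct a conformational ensemble
#'
#' An ensemble is an ordered list of equally sized `ca_trace` frames over the
#' same residues; frame 1 is the reference structure.
#'
#' @param frames list of `ca_trace` objects.
#' @param source_id text label.
#' @return Object of class `ca_ensemble`.
#' @export
ca_ensemble <- function(frames, source_id = "ensemble") {
  if (!length(frames)) stop("an ensemble needs at least one frame")
  if (!all(vapply(frames, inherits, TRUE, "ca_trace")))
    stop("all frames must be ca_trace objects")
  ref <- frames[[1L]]
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != nrow(ref$coords) ||
        !identical(frames[[i]]$residue_ids, ref$residue_ids))
      stop(sprintf(
        "inconsistent ensemble: frame %d does not match the reference residues", i))
  }
  structure(list(frames = frames, source_id = as.character(source_id)),
            class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat(sprintf("<ca_ensemble> %s: %d frames x %d residues\n",
              x$source_id, length(x$frames), nrow(x$frames[[1L]]$coords)))
  invisible(x)
}

#' @export
length.ca_ensemble <- function(x) length(x$frames)

# Split raw PDB lines into models.  Files without MODEL records are a single
# model.  Returns a list of character vectors (coordinate records only).
.split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts))
    stop("malformed multi-model PDB: unmatched MODEL record")
  lapply(seq_along(starts), function(i)
    lines[(starts[i] + 1L):(ends[i] - 1L)])
}

# Parse one model's lines with bio3d and apply the C-alpha selection policy.
.model_to_trace <- function(lines, chain, id) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(lines, "END"), tmp)
  pdb <- bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  if (is.null(chain)) chain <- atoms$chain[1L]
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (!nrow(atoms)) stop("chain '", chain, "' not found")
  is_ca <- atoms$elety == "CA" &
    !(!is.na(atoms$elesy) & atoms$elesy == "CA")  # drop calcium ions
  ca <- atoms[is_ca, , drop = FALSE]
  res_all <- unique(paste(atoms$resno, atoms$insert))
  res_ca <- unique(paste(ca$resno, ca$insert))
  if (length(setdiff(res_all, res_ca)))
    warning(length(setdiff(res_all, res_ca)),
            " residue(s) without a C-alpha atom skipped")
  if (!nrow(ca)) stop("empty trace: no C-alpha atoms in chain '", chain, "'")
  # altloc resolution: per residue keep highest occupancy, then first record
  key <- paste(ca$resno, ca$insert)
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  keep <- unlist(lapply(unique(key), function(k) {
    idx <- which(key == k)
    idx[which.max(occ[idx])]
  }), use.names = FALSE)
  keep <- sort(keep)
  ca <- ca[keep, , drop = FALSE]
  ca_trace(cbind(ca$x, ca$y, ca$z), residue_ids = ca$resno,
           chain_id = chain, id = id)
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts the ordered C-alpha coordinates of one chain and one model.
#' HETATM C-alpha records (e.g. selenomethionine) are included; calcium ions
#' are not.  Alternate locations are resolved to the highest occupancy, ties
#' to the first record; residues lacking a C-alpha are skipped with a
#' warning.  Insertion-code ordering follows the file.
#'
#' @param file path to a PDB file.
#' @param chain chain identifier; default: first chain in the file.
#' @param model 1-based model number (default 1).
#' @return A [ca_trace()].
#' @export
read_ca_trace <- function(file, chain = NULL, model = 1L) {
  lines <- readLines(file, warn = FALSE)
  models <- .split_models(lines)
  if (model < 1L || model > length(models))
    stop("model ", model, " not present (file has ", length(models), ")")
  .model_to_trace(models[[model]], chain,
                  id = sub("\\.pdb$", "", basename(file)))
}

#' Read a multi-model PDB file as an ensemble
#'
#' One frame per MODEL record (a single frame for single-model files), each
#' parsed with the same selection policy as [read_ca_trace()] and validated
#' for identical residue numbering across frames.
#'
#' @inheritParams read_ca_trace
#' @return A [ca_ensemble()].
#' @export
read_ensemble <- function(file, chain = NULL) {
  lines <- readLines(file, warn = FALSE)
  models <- .split_models(lines)
  id <- sub("\\.pdb$", "", basename(file))
  frames <- lapply(seq_along(models), function(i)
    .model_to_trace(models[[i]], chain, id = sprintf("%s.%d", id, i)))
  ca_ensemble(frames, source_id = id)
}

.pdb_atom_line <- function(serial, chain, resno, xyz) {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, " CA ", " ", "ALA", chain, resno, " ",
          xyz[1L], xyz[2L], xyz[3L], 1, 0, "C")
}

#' Write a trace or ensemble as a CA-only PDB file
#'
#' Residues are written as alanine C-alpha ATOM records; ensembles become
#' multi-model files (MODEL/ENDMDL).
#'
#' @param x a `ca_trace` or `ca_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(x, path) {
  trace_lines <- function(tr) {
    vapply(seq_len(nrow(tr$coords)), function(i)
      .pdb_atom_line(i, tr$chain_id, tr$residue_ids[i], tr$coords[i, ]), "")
  }
  if (inherits(x, "ca_trace")) {
    writeLines(c(trace_lines(x), "END"), path)
  } else if (inherits(x, "ca_ensemble")) {
    body <- unlist(lapply(seq_along(x$frames), function(m)
      c(sprintf("MODEL     %4d", m), trace_lines(x$frames[[m]]), "ENDMDL")))
    writeLines(c(body, "END"), path)
  } else stop("'x' must be a ca_trace or ca_ensemble")
  invisible(path)
}

#' Write a structure-string encoding
#'
#' FASTA carries the letter string (header: structure id, alphabet, method);
#' TSV adds the per-position fit error.  Encoding position i covers residues
#' i..i+3 of the trace.
#'
#' @param enc an `sa_encoding` (see [encode_local()]).
#' @param path output file.
#' @param format `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_encoding <- function(enc, path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(enc, "sa_encoding"))
  if (format == "fasta") {
    header <- sprintf(">%s alphabet=%s method=%s", enc$structure_id,
                      enc$alphabet, enc$method)
    if (!length(enc$letters)) {
      warning("empty encoding: writing header only")
      writeLines(header, path)
    } else {
      writeLines(c(header, paste(enc$letters, collapse = "")), path)
    }
  } else {
    df <- data.frame(pos = seq_along(enc$letters), letter = enc$letters,
                     error = enc$per_position_error)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a structure-string encoding written by [write_encoding()]
#'
#' @param path input file.
#' @param format `"fasta"` or `"tsv"`.
#' @return An `sa_encoding` (per-position errors are NA for FASTA input).
#' @export
read_encoding <- function(path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !startsWith(lines[1L], ">"))
      stop("not a FASTA encoding file")
    fields <- strsplit(sub("^>", "", lines[1L]), " ")[[1L]]
    get <- function(key) sub(paste0(key, "="), "",
                             grep(paste0("^", key, "="), fields, value = TRUE))
    letters <- if (length(lines) > 1L)
      strsplit(paste(lines[-1L], collapse = ""), "")[[1L]] else character()
    sa_encoding(letters, per_position_error = rep(NA_real_, length(letters)),
                structure_id = fields[1L], alphabet = get("alphabet"),
                method = get("method"))
  } else {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("integer", "character", "numeric"))
    sa_encoding(df$letter, per_position_error = df$error,
                structure_id = sub("\\.[^.]*$", "", basename(path)),
                alphabet = "unknown", method = "local")
  }
}

#' Write an OPTICS reachability profile as TSV
#'
#' Columns: walk position, original point index, reachability distance and
#' core distance (degrees; the undefined first reachability is written as
#' `Inf`).  The file plots directly as a reachability profile.
#'
#' @param optics an `optics_result` (see [optics_order()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reachability <- function(optics, path) {
  stopifnot(inherits(optics, "optics_result"))
  df <- data.frame(position = seq_along(optics$order), index = optics$order,
                   reachability = optics$reachability,
                   core_distance = optics$core_distance)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
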