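#' Construct a backbone structure model
#'
#' A `structure_model` is the unit that gets scored and classified: an ordered
#' single-chain protein backbone with N, CA, C (and optionally O) coordinates
#' per residue. Chain breaks (peptide C(i)-N(i+1) bond length outside
#' \[1, 2\] Angstrom) are detected on construction and recorded so that
#' dihedrals are never computed across a gap.
#'
#' @param id character model identifier.
#' @param residue_names character vector of 3-letter residue codes.
#' @param n,ca,c numeric matrices (n_res x 3) of backbone atom coordinates in
#'   Angstrom.
#' @param o optional carbonyl-oxygen coordinate matrix; rows may be `NA`.
#' @param chain_breaks optional logical vector; `TRUE` at position i flags a
#'   break between residues i and i+1. Detected from C-N distances when `NULL`.
#' @return an object of class `structure_model` with elements `id`,
#'   `residue_names`, `sequence` (1-letter string, `X` for nonstandard),
#'   `n`, `ca`, `c`, `o`, `chain_breaks`.
#' @export
structure_model <- function(id, residue_names, n, ca, c, o = NULL,
                            chain_breaks = NULL) {
  n  <- as_coord_matrix(n,  "n")
  ca <- as_coord_matrix(ca, "ca")
  c  <- as_coord_matrix(c,  "c")
  nres <- length(residue_names)
  if (nres < 3L)
    stop("a structure model needs at least 3 residues, got ", nres)
  if (nrow(n) != nres || nrow(ca) != nres || nrow(c) != nres)
    stop("coordinate matrices must have one row per residue")
  if (!all(is.finite(n)) || !all(is.finite(ca)) || !all(is.finite(c)))
    stop("backbone coordinates must be finite")
  if (is.null(o)) {
    o <- matrix(NA_real_, nres, 3L)
  } else {
    o <- as_coord_matrix(o, "o")
    if (nrow(o) != nres) stop("'o' must have one row per residue")
  }
  if (is.null(chain_breaks)) {
    cn <- sqrt(rowSums((n[-1L, , drop = FALSE] - c[-nres, , drop = FALSE])^2))
    chain_breaks <- c(cn < 1.0 | cn > 2.0, FALSE)
  } else {
    chain_breaks <- as.logical(chain_breaks)
    if (length(chain_breaks) != nres) stop("'chain_breaks' length mismatch")
  }
  seq1 <- .AA3[toupper(residue_names)]
  nonstd <- is.na(seq1)
  seq1[nonstd] <- "X"
  structure(
    list(
      id = as.character(id), residue_names = toupper(residue_names),
      sequence = paste0(seq1, collapse = ""),
      n = n, ca = ca, c = c, o = o,
      chain_breaks = chain_breaks, nonstandard = unname(nonstd)
    ),
    class = "structure_model"
  )
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("'", what, "' must be an n x 3 matrix")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$id, ": ", length(x$residue_names),
      " residues", if (any(x$chain_breaks)) sprintf(
        ", %d chain break(s)", sum(x$chain_breaks)) else "", "\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure model
#' @param x a `structure_model`.
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "structure_model"))
  length(x$residue_names)
}

# PDB fixed columns (1-based, inclusive): record 1-6, serial 7-11, name 13-16,
# altLoc 17, resName 18-20, chainID 22, resSeq 23-26, iCode 27, x/y/z 31-54.
parse_pdb_atom <- function(line) {
  list(
    name    = trimws(substr(line, 13L, 16L)),
    altloc  = substr(line, 17L, 17L),
    resname = trimws(substr(line, 18L, 20L)),
    chain   = substr(line, 22L, 22L),
    resseq  = trimws(substr(line, 23L, 26L)),
    icode   = substr(line, 27L, 27L),
    x = as.numeric(substr(line, 31L, 38L)),
    y = as.numeric(substr(line, 39L, 46L)),
    z = as.numeric(substr(line, 47L, 54L))
  )
}

#' Read a backbone model from a PDB file
#'
#' Reads the first MODEL of a single-chain PDB file. Only `ATOM` records are
#' used (`HETATM` skipped); alternate locations other than blank or `A` are
#' discarded; insertion codes are retained in the residue key. Residues
#' missing any of N, CA or C are dropped with a warning and a chain break is
#' flagged on their neighbours.
#'
#' @param path path to a PDB file.
#' @param model_policy currently only `"first"`: keep the first MODEL block.
#' @param id model identifier; defaults to the file name without extension.
#' @return a [structure_model].
#' @export
read_pdb <- function(path, model_policy = c("first"), id = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  # first MODEL only: cut at the first ENDMDL if present
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  atoms <- lines[substr(lines, 1L, 6L) == "ATOM  "]
  if (!length(atoms)) stop("parse error: no ATOM records in ", path)

  recs <- lapply(atoms, parse_pdb_atom)
  altloc <- vapply(recs, `[[`, "", "altloc")
  recs <- recs[altloc %in% c(" ", "", "A")]
  if (!length(recs)) stop("parse error: no usable ATOM records in ", path)

  chains <- unique(vapply(recs, `[[`, "", "chain"))
  if (length(chains) > 1L)
    stop("expected a single chain, found chains: ",
         paste(sQuote(trimws(chains)), collapse = ", "))

  key <- vapply(recs, function(r) paste0(r$chain, "|", r$resseq, "|", r$icode), "")
  keys <- unique(key)  # file order
  nres <- length(keys)
  resname <- character(nres)
  crd <- list(N = matrix(NA_real_, nres, 3L), CA = matrix(NA_real_, nres, 3L),
              C = matrix(NA_real_, nres, 3L), O = matrix(NA_real_, nres, 3L))
  for (j in seq_along(recs)) {
    r <- recs[[j]]
    i <- match(key[j], keys)
    resname[i] <- r$resname
    if (r$name %in% names(crd) && is.na(crd[[r$name]][i, 1L]))
      crd[[r$name]][i, ] <- c(r$x, r$y, r$z)
  }

  complete <- !is.na(crd$N[, 1L]) & !is.na(crd$CA[, 1L]) & !is.na(crd$C[, 1L])
  forced_break <- logical(sum(complete))
  if (any(!complete)) {
    warning("dropped ", sum(!complete),
            " residue(s) missing N/CA/C in ", basename(path))
    # a dropped residue leaves a gap: flag the surviving predecessor
    kept_idx <- which(complete)
    gap_after <- vapply(seq_along(kept_idx), function(k) {
      k < length(kept_idx) && kept_idx[k + 1L] != kept_idx[k] + 1L
    }, logical(1L))
    forced_break <- gap_after
  }
  if (sum(complete) < 3L)
    stop("parse error: fewer than 3 complete backbone residues in ", path)

  m <- structure_model(
    id, resname[complete],
    crd$N[complete, , drop = FALSE],
    crd$CA[complete, , drop = FALSE],
    crd$C[complete, , drop = FALSE],
    crd$O[complete, , drop = FALSE]
  )
  m$chain_breaks <- m$chain_breaks | forced_break
  m
}

#' Write a backbone model as a PDB file
#'
#' Emits standard fixed-width ATOM records (N, CA, C and O when present) with
#' a TER/END footer. Coordinates carry 3 decimals, so a read/write round trip
#' reproduces coordinates to 1e-3 Angstrom.
#'
#' @param model a [structure_model].
#' @param path output file path.
#' @param chain_id single-character chain identifier.
#' @return invisibly, the path.
#' @export
write_pdb <- function(model, path, chain_id = "A") {
  stopifnot(inherits(model, "structure_model"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  serial <- 0L
  fmt <- "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  nres <- n_residues(model)
  out <- character(0L)
  atom_order <- c(N = "n", CA = "ca", C = "c", O = "o")
  for (i in seq_len(nres)) {
    for (an in names(atom_order)) {
      xyz <- model[[atom_order[[an]]]][i, ]
      if (anyNA(xyz)) next
      serial <- serial + 1L
      out <- c(out, sprintf(
        fmt, serial, paste0(" ", an), " ", model$residue_names[i], chain_id,
        i, " ", xyz[1L], xyz[2L], xyz[3L], 1, 0, substr(an, 1L, 1L)))
    }
  }
  writeLines(c(out, "TER", "END"), con)
  invisible(path)
}

#' Load an external per-model score table
#'
#' Ingests a CSV of externally computed per-model energy terms (for example a
#' Rosetta talaris2013 score file re-exported as CSV) keyed by `model_id`.
#' Term columns are kept verbatim; constant columns (such as the
#' composition-only reference energy `ref`) load unchanged and simply come out
#' non-significant downstream.
#'
#' @param path CSV path with header `model_id` plus one or more numeric term
#'   columns.
#' @return a data.frame with character `model_id` and numeric term columns.
#' @export
load_score_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"model_id" %in% names(df))
    stop("score table must have a 'model_id' header column")
  if (ncol(df) < 2L) stop("score table needs at least one term column")
  if (anyDuplicated(df$model_id))
    stop("duplicate model_id in score table: ",
         paste(unique(df$model_id[duplicated(df$model_id)]), collapse = ", "))
  df$model_id <- as.character(df$model_id)
  for (nm in setdiff(names(df), "model_id")) {
    v <- df[[nm]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (!is.numeric(v) || anyNA(v))
      stop("non-numeric cell in term column ", sQuote(nm))
    df[[nm]] <- as.numeric(v)
  }
  df
}
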