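# Structure I/O: PDB reading/writing (via bio3d), atom selection, and the
# registry of fragment residue ranges used throughout the co-localization and
# BiFC deletion-construct experiments.

#' Create a structure object from an atom table
#'
#' A `structure3d` is the package's atomic-coordinate container: an ordered
#' atom table plus a free-text identifier. Iteration order is stable and, for
#' structures read from disk, equals file order.
#'
#' @param atoms data.frame with columns `name` (atom label, e.g. "CA"),
#'   `element` (chemical symbol), `x`, `y`, `z` (angstrom), `resno` (integer
#'   author residue number), `resid` (3-letter residue code), `chain`
#'   (single-character chain label). A logical `is_heavy` column is derived
#'   from `element` if absent.
#' @param id free-text label.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, id = "structure") {
  req <- c("name", "element", "x", "y", "z", "resno", "resid", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop_gd("atom table lacks column(s): %s", paste(miss, collapse = ", "),
            class = "groovedock_value_error")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop_gd("non-finite coordinates in atom table", class = "groovedock_value_error")
  if (any(atoms$resno != as.integer(atoms$resno)))
    stop_gd("residue numbers must be integers", class = "groovedock_value_error")
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$is_heavy)) atoms$is_heavy <- toupper(atoms$element) != "H"
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop_gd("duplicate (chain, resno, atom name) triple: %s", key[duplicated(key)][1],
            class = "groovedock_value_error")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure3d> '%s': %d atoms, %d residues, chains: %s\n",
              x$id, nrow(a), length(unique(paste(a$chain, a$resno))),
              paste(sort(unique(a$chain)), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `structure3d`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Atom coordinates as a matrix
#' @param s a `structure3d`.
#' @param heavy_only drop hydrogens.
#' @return n x 3 numeric matrix (angstrom).
#' @export
coords <- function(s, heavy_only = FALSE) {
  a <- s$atoms
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Define a labelled helix segment
#'
#' Residue ranges are inclusive on both ends and use author numbering, matching
#' the "residues 151-223" convention of the fragment constructs.
#'
#' @param chain single-character chain label.
#' @param start,end first and last residue number (inclusive).
#' @param label free text, e.g. "TM8" or "GluN1-M4".
#' @return object of class `helix_segment`.
#' @export
helix_segment <- function(chain, start, end, label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop_gd("invalid segment: start (%s) must be <= end (%s)", start, end,
            class = "groovedock_value_error")
  structure(list(chain = as.character(chain), start = start, end = end,
                 label = as.character(label)), class = "helix_segment")
}

#' @export
print.helix_segment <- function(x, ...) {
  cat(sprintf("<helix_segment> %s %s:%d-%d\n", x$label, x$chain, x$start, x$end))
  invisible(x)
}

#' Transmembrane topology for one chain
#'
#' An ordered list of non-overlapping helix segments, ascending in residue
#' number (e.g. the 11 TM helices of a short ND2-like bundle).
#'
#' @param segments list of [helix_segment()] on one chain.
#' @return object of class `tm_topology`.
#' @export
tm_topology <- function(segments) {
  if (length(segments) == 0) stop_gd("empty topology", class = "groovedock_value_error")
  ch <- unique(vapply(segments, `[[`, "", "chain"))
  if (length(ch) != 1)
    stop_gd("topology must cover a single chain", class = "groovedock_value_error")
  st <- vapply(segments, `[[`, 0L, "start")
  en <- vapply(segments, `[[`, 0L, "end")
  o <- order(st)
  st <- st[o]; en <- en[o]; segments <- segments[o]
  if (any(st[-1] <= en[-length(en)]))
    stop_gd("topology segments overlap or are unordered", class = "groovedock_value_error")
  structure(list(segments = segments, chain = ch), class = "tm_topology")
}

#' Read a PDB file
#'
#' Parses fixed-column ATOM records via \pkg{bio3d}. Only the first MODEL is
#' used; HETATM records are skipped by default; alternate locations other than
#' blank/'A' are dropped with a warning; insertion codes are rejected (the
#' author-numbered structures in scope do not use them, and silent mishandling
#' is worse than an error).
#'
#' @param path PDB file path.
#' @param keep_hetatm also keep HETATM records.
#' @return a [structure3d()].
#' @export
read_pdb <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path))
    stop_gd("cannot read PDB file '%s'", path, class = "groovedock_io_error")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  if (!keep_hetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0)
    stop_gd("no ATOM records in '%s'", path, class = "groovedock_empty_error")
  bad_alt <- !(is.na(a$alt) | a$alt %in% c("", "A"))
  if (any(bad_alt)) {
    warning(sprintf("%d atom(s) with altloc other than blank/'A' skipped", sum(bad_alt)))
    a <- a[!bad_alt, , drop = FALSE]
  }
  if (any(!(is.na(a$insert) | a$insert == "")))
    stop_gd("insertion codes are not supported (found in '%s')", path,
            class = "groovedock_value_error")
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  elem[is.na(elem) | elem == ""] <- substr(trimws(a$elety[is.na(elem) | elem == ""]), 1, 1)
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- " "
  structure3d(
    data.frame(name = trimws(a$elety), element = trimws(elem),
               x = a$x, y = a$y, z = a$z,
               resno = a$resno, resid = trimws(a$resid), chain = chain,
               stringsAsFactors = FALSE),
    id = basename(path))
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-column ATOM records (single model, terminated by END)
#' with coordinates at 3 decimals.
#'
#' @param s a [structure3d()]; must be non-empty.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  if (!inherits(s, "structure3d") || n_atoms(s) == 0)
    stop_gd("refusing to write an empty structure", class = "groovedock_empty_error")
  a <- s$atoms
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     chain = a$chain, elesy = a$element,
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_gd("cannot write PDB file '%s': %s", path, conditionMessage(ok),
            class = "groovedock_io_error")
  invisible(path)
}

#' Select a chain or a residue range from a structure
#'
#' @param s a [structure3d()].
#' @param chain chain label, must exist in `s`.
#' @param segment optional [helix_segment()]; if given, restricts to residues
#'   `start..end` (inclusive). The segment's own chain field is ignored in
#'   favour of `chain`.
#' @return a [structure3d()] with atom order preserved.
#' @export
select_atoms <- function(s, chain, segment = NULL) {
  a <- s$atoms
  if (!chain %in% a$chain)
    stop_gd("chain '%s' not present (have: %s)", chain,
            paste(sort(unique(a$chain)), collapse = " "),
            class = "groovedock_lookup_error")
  keep <- a$chain == chain
  if (!is.null(segment)) keep <- keep & a$resno >= segment$start & a$resno <= segment$end
  if (!any(keep))
    stop_gd("selection chain '%s'%s matches zero atoms", chain,
            if (is.null(segment)) "" else sprintf(" residues %d-%d", segment$start, segment$end),
            class = "groovedock_empty_error")
  structure3d(a[keep, , drop = FALSE], id = sprintf("%s[%s]", s$id, chain))
}

# Residue ranges of the deletion/truncation constructs (author numbering).
# ND2 fragments from the co-localization construct series; GluN1-M4 spans the
# residues between the two CTD/M4 truncation stop codons (837 and 813).
.fragment_registry <- list(
  "ND2-TM-6-11"     = c(chain = "A", start = 151, end = 347),
  "ND2-TM-10-11"    = c(chain = "A", start = 250, end = 347),
  "ND2-TM-6-8+loop" = c(chain = "A", start = 151, end = 240),
  "ND2-TM-6-8"      = c(chain = "A", start = 151, end = 223),
  "ND2-TM-6-7"      = c(chain = "A", start = 151, end = 200),
  "ND2-TM-7-8"      = c(chain = "A", start = 175, end = 223),
  "GluN1-M4"        = c(chain = "B", start = 813, end = 836),
  "ND2-Src-anchor"  = c(chain = "A", start = 239, end = 321)
)

#' Residue bounds of a registered fragment
#'
#' Returns the author-numbered residue range of a named construct fragment,
#' e.g. `fragment_bounds("ND2-TM-6-8")` is `c(151, 223)`.
#'
#' @param name fragment label; see [fragment_registry()] for the known set.
#' @return integer vector `c(start, end)`.
#' @export
fragment_bounds <- function(name) {
  e <- .fragment_registry[[name]]
  if (is.null(e))
    stop_gd("unknown fragment '%s'; known: %s", name,
            paste(names(.fragment_registry), collapse = ", "),
            class = "groovedock_lookup_error")
  c(start = as.integer(e[["start"]]), end = as.integer(e[["end"]]))
}

#' The full fragment registry as a data.frame
#' @return data.frame with columns label, chain, start, end.
#' @export
fragment_registry <- function() {
  data.frame(label = names(.fragment_registry),
             chain = vapply(.fragment_registry, `[[`, "", "chain"),
             start = vapply(.fragment_registry, function(x) as.integer(x[["start"]]), 0L),
             end   = vapply(.fragment_registry, function(x) as.integer(x[["end"]]), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Load additional fragment definitions from a plain-text table
#'
#' Format: tab-separated columns `label`, `chain`, `start`, `end`; lines
#' starting with '#' are comments.
#'
#' @param path TSV file path.
#' @return data.frame of the loaded fragments (also usable with
#'   [helix_segment()]).
#' @export
read_fragment_table <- function(path) {
  if (!file.exists(path))
    stop_gd("cannot read fragment table '%s'", path, class = "groovedock_io_error")
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  req <- c("label", "chain", "start", "end")
  if (!all(req %in% names(d)))
    stop_gd("fragment table needs columns: %s", paste(req, collapse = ", "),
            class = "groovedock_value_error")
  if (any(d$start > d$end))
    stop_gd("fragment table has start > end", class = "groovedock_value_error")
  d
}
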