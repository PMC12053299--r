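## Structure and coupling-table I/O.
##
## Fixed unit conventions: Angstrom for coordinates, Hz for couplings,
## kcal/mol for energies. The table dialect is whitespace/TAB-delimited
## with a header row, '#' comments and the literal "NA" as the
## missing-value sentinel.

.err <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "rdctensorError")))
}

#' Construct a Conformer
#'
#' @param id conformer identifier.
#' @param label character vector of unique atom labels.
#' @param element chemical symbols; used to look up standard atomic
#'   weights when \code{mass} is not given.
#' @param xyz numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param mass atomic masses (u); defaults to standard atomic weights.
#' @param eRel optional relative energy (kcal/mol).
#' @return a \linkS4class{Conformer}.
#' @export
conformer <- function(id, label, element, xyz, mass = NULL,
                      eRel = NA_real_) {
  xyz <- as.matrix(xyz)
  if (is.null(mass)) mass <- atomicMass(element)
  new("Conformer", id = as.character(id),
      atoms = data.frame(label = as.character(label),
                         element = as.character(element),
                         mass = as.numeric(mass),
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE),
      eRel = as.numeric(eRel))
}

.coordMatrix <- function(conf) {
  a <- atoms(conf)
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$label
  m
}

#' Read a conformer from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then
#' \code{element x y z} rows. An optional fifth column is taken verbatim
#' as the atom label; otherwise labels are auto-generated as
#' element+index (C1, H2, ...). A token \code{E_rel=<value>} on the
#' comment line is parsed as the relative energy in kcal/mol.
#'
#' @param path file path.
#' @param id conformer id; defaults to the file name without extension.
#' @return a \linkS4class{Conformer}.
#' @export
readXYZ <- function(path, id = NULL) {
  if (!file.exists(path)) .err("rdcFileError", paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2)
    .err("rdcXYZCountError", "XYZ file has fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    .err("rdcXYZCountError",
         paste0("malformed atom-count line 1: ", sQuote(lines[1])))
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    .err("rdcXYZCountError",
         sprintf("count line declares %d atoms but %d atom rows found (first row is line 3)",
                 n, length(body)))
  toks <- strsplit(trimws(body), "[ \t]+")
  element <- character(n); lab <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) < 4)
      .err("rdcXYZCoordError", sprintf("atom row %d has fewer than 4 fields", i))
    element[i] <- tk[1]
    v <- suppressWarnings(as.numeric(tk[2:4]))
    if (anyNA(v))
      .err("rdcXYZCoordError",
           sprintf("cannot parse coordinates on atom row %d: %s", i, body[i]))
    xyz[i, ] <- v
    lab[i] <- if (length(tk) >= 5) tk[5] else ""
  }
  if (!all(element %in% names(.ATOMIC_MASS)))
    .err("rdcElementError",
         paste("unknown element symbol(s):",
               paste(setdiff(element, names(.ATOMIC_MASS)), collapse = ", ")))
  if (any(!nzchar(lab))) {
    auto <- paste0(element, seq_len(n))
    lab[!nzchar(lab)] <- auto[!nzchar(lab)]
  }
  eRel <- NA_real_
  m <- regmatches(lines[2], regexpr("E_rel=[-0-9.eE+]+", lines[2]))
  if (length(m) == 1) eRel <- as.numeric(sub("E_rel=", "", m))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  conformer(id, lab, element, xyz, eRel = eRel)
}

#' Write a conformer as an XYZ file
#'
#' Labels are emitted as a fifth column so that
#' \code{\link{readXYZ}} round-trips them; a known relative energy is
#' recorded on the comment line as \code{E_rel=<value>}.
#'
#' @param conf a \linkS4class{Conformer}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeXYZ <- function(conf, path) {
  a <- atoms(conf)
  comment <- conf@id
  if (!is.na(relEnergy(conf)))
    comment <- sprintf("%s E_rel=%.6f", comment, relEnergy(conf))
  rows <- sprintf("%-2s %14.6f %14.6f %14.6f %s",
                  a$element, a$x, a$y, a$z, a$label)
  writeLines(c(as.character(nrow(a)), comment, rows), path)
  invisible(path)
}

#' Read a conformer from a PDB file (minimal subset)
#'
#' Reads ATOM/HETATM records of the first MODEL only; uses atom name,
#' element and coordinates; occupancy, altloc and everything else are
#' ignored. The element is taken from columns 77-78 when present, else
#' inferred from the atom name.
#'
#' @param path file path.
#' @param id conformer id; defaults to the file name without extension.
#' @return a \linkS4class{Conformer}.
#' @export
readPDB <- function(path, id = NULL) {
  if (!file.exists(path)) .err("rdcFileError", paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  endm <- grep("^ENDMDL", lines)
  if (length(endm) > 0) lines <- lines[seq_len(endm[1] - 1)]
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) < 2)
    .err("rdcPDBError", "fewer than 2 ATOM/HETATM records in first model")
  name <- trimws(substr(rec, 13, 16))
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    .err("rdcPDBError", "unparseable coordinates in ATOM/HETATM record")
  element <- trimws(substr(rec, 77, 78))
  guess <- sub("^([A-Za-z]).*", "\\1", name)
  element[!nzchar(element)] <- guess[!nzchar(element)]
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  element <- trimws(element)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lab <- make.unique(name, sep = "_")
  conformer(id, lab, element, cbind(x, y, z))
}

## ---- coupling tables -------------------------------------------------

.RDC_COLS <- c("atom1", "atom2", "type", "J", "sigJ", "T", "sigT",
               "D", "sigD", "include")

#' Construct an RDCDataset
#'
#' @param atom1,atom2 atom labels of each pair.
#' @param type coupling class, one of \code{"CH"}, \code{"CH2-member"},
#'   \code{"CH3-methyl"}, \code{"CC"}, \code{"generic"}.
#' @param J,sigJ,T,sigT,D,sigD couplings and errors in Hz (NA if absent).
#' @param include logical, whether the record enters fits.
#' @param meta provenance list.
#' @return an \linkS4class{RDCDataset}.
#' @export
rdcDataset <- function(atom1, atom2, type = "CH", J = NA_real_,
                       sigJ = NA_real_, T = NA_real_, sigT = NA_real_,
                       D = NA_real_, sigD = NA_real_, include = TRUE,
                       meta = list()) {
  n <- length(atom1)
  r <- data.frame(atom1 = as.character(atom1), atom2 = as.character(atom2),
                  type = rep_len(as.character(type), n),
                  J = rep_len(as.numeric(J), n),
                  sigJ = rep_len(as.numeric(sigJ), n),
                  T = rep_len(as.numeric(T), n),
                  sigT = rep_len(as.numeric(sigT), n),
                  D = rep_len(as.numeric(D), n),
                  sigD = rep_len(as.numeric(sigD), n),
                  include = rep_len(as.logical(include), n),
                  stringsAsFactors = FALSE)
  new("RDCDataset", records = r, meta = meta)
}

#' Read a coupling table
#'
#' Whitespace/TAB-delimited text with a header row naming columns from
#' \code{atom1 atom2 type J sigJ T sigT D sigD include}; \code{'#'}
#' starts a comment and \code{"NA"} is the missing-value sentinel.
#' Missing optional columns become absent fields; \code{include}
#' defaults to \code{TRUE}.
#'
#' @param path file path.
#' @return an \linkS4class{RDCDataset}.
#' @export
readRDCTable <- function(path) {
  if (!file.exists(path)) .err("rdcFileError", paste("file not found:", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(sub("#.*$", "", raw))))
  if (length(keep) == 0) .err("rdcTableError", "table has no header row")
  lines <- sub("#.*$", "", raw[keep])
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (!all(c("atom1", "atom2") %in% hdr))
    .err("rdcTableError", "mandatory columns atom1 and atom2 missing")
  unknown <- setdiff(hdr, .RDC_COLS)
  if (length(unknown) > 0)
    .err("rdcTableError",
         paste("unknown column(s):", paste(unknown, collapse = ", ")))
  n <- length(lines) - 1L
  out <- data.frame(atom1 = character(n), atom2 = character(n),
                    type = rep("CH", n), J = rep(NA_real_, n),
                    sigJ = rep(NA_real_, n), T = rep(NA_real_, n),
                    sigT = rep(NA_real_, n), D = rep(NA_real_, n),
                    sigD = rep(NA_real_, n), include = rep(TRUE, n),
                    stringsAsFactors = FALSE)
  numcols <- c("J", "sigJ", "T", "sigT", "D", "sigD")
  for (i in seq_len(n)) {
    srcline <- keep[i + 1L]
    tk <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    if (length(tk) < length(hdr))
      .err("rdcTableError",
           sprintf("row on line %d has %d fields, expected %d (missing %s?)",
                   srcline, length(tk), length(hdr),
                   paste(hdr[seq(length(tk) + 1L, length(hdr))],
                         collapse = ", ")))
    row <- as.list(tk[seq_along(hdr)])
    names(row) <- hdr
    for (cc in intersect(hdr, numcols)) {
      v <- row[[cc]]
      if (identical(v, "NA")) { out[[cc]][i] <- NA_real_; next }
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num))
        .err("rdcTableError",
             sprintf("non-numeric value %s in column %s on line %d",
                     sQuote(v), cc, srcline))
      out[[cc]][i] <- num
    }
    out$atom1[i] <- row$atom1
    out$atom2[i] <- row$atom2
    if ("type" %in% hdr) out$type[i] <- row$type
    if ("include" %in% hdr)
      out$include[i] <- toupper(row$include) %in% c("TRUE", "T", "1", "YES")
  }
  new("RDCDataset", records = out, meta = list(source = path))
}

#' Write a coupling table
#'
#' Deterministic column order (atom1 atom2 type J sigJ T sigT D sigD
#' include), couplings at 0.01 Hz resolution, errors at 0.001 Hz,
#' \code{"NA"} sentinel for absent values. The output is re-readable by
#' \code{\link{readRDCTable}}.
#'
#' @param ds an \linkS4class{RDCDataset}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeRDCTable <- function(ds, path) {
  r <- records(ds)
  fmt <- function(v, digits) ifelse(is.na(v), "NA", sprintf(paste0("%.", digits, "f"), v))
  lines <- paste(.RDC_COLS, collapse = "\t")
  if (nrow(r) > 0) {
    body <- paste(r$atom1, r$atom2, r$type,
                  fmt(r$J, 2), fmt(r$sigJ, 3), fmt(r$T, 2), fmt(r$sigT, 3),
                  fmt(r$D, 2), fmt(r$sigD, 3),
                  ifelse(r$include, "TRUE", "FALSE"), sep = "\t")
    lines <- c(lines, body)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) .err("rdcFileError", paste("cannot write", path))
  invisible(path)
}

#' Read and write population tables
#'
#' Same delimited dialect as the coupling tables, with columns
#' \code{conf eRel pRaw group} (\code{group} optional, \code{"NA"} for
#' unassigned).
#'
#' @param path file path.
#' @return \code{readPopulationTable}: a \linkS4class{PopulationTable}.
#' @export
readPopulationTable <- function(path) {
  if (!file.exists(path)) .err("rdcFileError", paste("file not found:", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(sub("#.*$", "", raw))))
  if (length(keep) < 1) .err("rdcTableError", "population table is empty")
  lines <- sub("#.*$", "", raw[keep])
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (!all(c("conf", "pRaw") %in% hdr))
    .err("rdcTableError", "population table needs columns conf and pRaw")
  toks <- lapply(strsplit(trimws(lines[-1]), "[ \t]+"), function(tk) {
    row <- as.list(tk[seq_along(hdr)]); names(row) <- hdr; row
  })
  getnum <- function(cc, default = NA_real_) {
    if (!cc %in% hdr) return(rep(default, length(toks)))
    vapply(toks, function(r) {
      if (identical(r[[cc]], "NA")) NA_real_
      else suppressWarnings(as.numeric(r[[cc]]))
    }, numeric(1))
  }
  getchr <- function(cc) {
    if (!cc %in% hdr) return(rep(NA_character_, length(toks)))
    v <- vapply(toks, function(r) r[[cc]], character(1))
    v[v == "NA"] <- NA_character_
    v
  }
  populationTable(conf = getchr("conf"), eRel = getnum("eRel"),
                  pRaw = getnum("pRaw"), group = getchr("group"))
}

#' @rdname readPopulationTable
#' @param tbl a \linkS4class{PopulationTable}.
#' @export
writePopulationTable <- function(tbl, path) {
  cf <- conformerTable(tbl)
  fmt <- function(v, d) ifelse(is.na(v), "NA", sprintf(paste0("%.", d, "f"), v))
  g <- ifelse(is.na(cf$group), "NA", cf$group)
  lines <- c("conf\teRel\tpRaw\tgroup",
             paste(cf$conf, fmt(cf$eRel, 3), fmt(cf$pRaw, 4), g, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
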