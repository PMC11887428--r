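#' Read a molecular structure file
#'
#' Supported formats: SDF/MOL V2000 (atoms, bonds, `M CHG` formal charges
#' and a `> <PARTIAL_CHARGES>` property block, one float per atom line),
#' PDB (`ATOM`/`HETATM` records; bonds perceived from distances), and XYZ
#' with an extended comment line `charge=<int>` plus an optional JSON
#' sidecar `<file>.json` carrying `formal_charges` and `partial_charges`
#' arrays.  Explicit hydrogens are preserved; they are never added.
#'
#' When the file carries no bond table (XYZ, bond-less PDB), bonds are
#' perceived with the covalent-radius rule: two atoms are bonded when
#' their distance is below 1.3 times the sum of their covalent radii
#' (radius table: [element_table()]).
#'
#' @param path file path.
#' @param format `"sdf"`, `"pdb"`, `"xyz"`, or `"auto"` (by extension).
#' @return A [molecule()].
#' @export
read_structure <- function(path, format = c("auto", "sdf", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", pdb = "pdb", xyz = "xyz",
                     stop("cannot infer format from extension '.", ext, "'",
                          call. = FALSE))
  }
  switch(format,
         sdf = read_sdf(path)[[1]],
         pdb = read_pdb(path),
         xyz = read_xyz(path))
}

#' Write a molecular structure file
#'
#' Inverse of [read_structure()]; SDF and XYZ round-trip coordinates to
#' 1e-4 Angstrom, PDB to its fixed-width 1e-3 precision.  Partial charges,
#' when present, are serialized as an SDF `> <PARTIAL_CHARGES>` property
#' block or an XYZ JSON sidecar.
#'
#' @param m a [molecule()].
#' @param path output file path.
#' @param format `"sdf"`, `"pdb"`, `"xyz"`, or `"auto"` (by extension).
#' @param properties named list of extra SDF property blocks.
#' @return `path`, invisibly.
#' @export
write_structure <- function(m, path, format = c("auto", "sdf", "pdb", "xyz"),
                            properties = list()) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", pdb = "pdb", xyz = "xyz",
                     stop("cannot infer format from extension '.", ext, "'",
                          call. = FALSE))
  }
  switch(format,
         sdf = writeLines(sdf_record(m, properties), path),
         pdb = write_pdb(m, path),
         xyz = write_xyz(m, path))
  invisible(path)
}

## ---- SDF ------------------------------------------------------------------

## all records of an SDF file as a list of molecules; ChemmineR parses the
## atom/bond blocks, the raw lines supply M CHG and multi-line properties
## (which ChemmineR does not retain in full).
read_sdf <- function(path) {
  raw <- readLines(path, warn = FALSE)
  set <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop("SDF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  starts <- c(1L, which(raw == "$$$$") + 1L)
  starts <- starts[starts <= length(raw)]
  out <- vector("list", length(set))
  for (r in seq_along(set)) {
    sdf <- set[[r]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_\\d+$", "", rownames(ab))
    counts_ln <- starts[r] + 3L
    n_declared <- suppressWarnings(as.integer(substr(raw[counts_ln], 1, 3)))
    if (is.na(n_declared) || n_declared != nrow(ab))
      stop("SDF parse error at line ", counts_ln, ": atom count mismatch",
           call. = FALSE)
    atoms <- data.frame(element = el,
                        x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        formal_charge = 0L, row.names = NULL)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) NULL else
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    # record slice of the raw file, for M CHG and property blocks
    end <- if (r < length(starts)) starts[r + 1L] - 1L else length(raw)
    rec <- raw[starts[r]:end]
    for (ln in grep("^M  CHG", rec, value = TRUE)) {
      f <- scan(text = sub("^M  CHG\\s*\\d+", "", ln), quiet = TRUE)
      idx <- f[seq(1, length(f), 2)]; chg <- f[seq(2, length(f), 2)]
      atoms$formal_charge[idx] <- as.integer(chg)
    }
    props <- parse_sdf_properties(rec)
    if (!is.null(props$PARTIAL_CHARGES)) {
      pc <- as.numeric(props$PARTIAL_CHARGES)
      if (length(pc) == nrow(atoms)) atoms$partial_charge <- pc
    }
    label <- if (nzchar(rec[1])) rec[1] else sprintf("sdf_record_%d", r)
    mol <- molecule(atoms, bonds, label = label)
    attr(mol, "sdf_properties") <- props
    out[[r]] <- mol
  }
  out
}

parse_sdf_properties <- function(rec) {
  hdr <- grep("^> *<", rec)
  props <- list()
  for (h in hdr) {
    name <- sub("^> *<([^>]+)>.*$", "\\1", rec[h])
    vals <- character()
    k <- h + 1L
    while (k <= length(rec) && nzchar(rec[k]) && rec[k] != "$$$$") {
      vals <- c(vals, rec[k]); k <- k + 1L
    }
    props[[name]] <- vals
  }
  props
}

sdf_record <- function(m, properties = list()) {
  n <- n_atoms(m); nb <- nrow(m$bonds)
  lines <- c(m$label, "  glyccs", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              m$atoms$x[i], m$atoms$y[i], m$atoms$z[i],
                              m$atoms$element[i]))
  }
  for (b in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", m$bonds$a1[b], m$bonds$a2[b],
                              m$bonds$order[b]))
  }
  chg <- which(m$atoms$formal_charge != 0L)
  while (length(chg) > 0) {
    take <- head(chg, 8)
    lines <- c(lines, paste0(sprintf("M  CHG%3d", length(take)),
                             paste0(sprintf("%4d%4d", take,
                                            m$atoms$formal_charge[take]),
                                    collapse = "")))
    chg <- chg[-seq_along(take)]
  }
  lines <- c(lines, "M  END")
  if (!all(is.na(m$atoms$partial_charge)))
    properties <- c(list(PARTIAL_CHARGES = sprintf("%.6f", m$atoms$partial_charge)),
                    properties)
  for (nm in names(properties)) {
    lines <- c(lines, sprintf("> <%s>", nm), as.character(properties[[nm]]), "")
  }
  c(lines, "$$$$")
}

## multi-record SDF writer (conformer ensembles)
write_sdf_multi <- function(mols, path, properties_list = NULL) {
  out <- unlist(lapply(seq_along(mols), function(i) {
    sdf_record(mols[[i]],
               if (is.null(properties_list)) list() else properties_list[[i]])
  }))
  writeLines(out, path)
  invisible(path)
}

## ---- PDB ------------------------------------------------------------------

read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  el <- trimws(a$elesy)
  el[is.na(el) | el == ""] <- trimws(substr(a$elety[is.na(el) | el == ""], 1, 1))
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  atoms <- data.frame(element = el, x = a$x, y = a$y, z = a$z,
                      formal_charge = 0L)
  bonds <- perceive_bonds(atoms)
  molecule(atoms, bonds, label = sub("\\.pdb$", "", basename(path),
                                     ignore.case = TRUE))
}

write_pdb <- function(m, path) {
  lines <- character()
  for (i in seq_len(n_atoms(m))) {
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i, substr(paste0(m$atoms$element[i], i), 1, 4),
      m$atoms$x[i], m$atoms$y[i], m$atoms$z[i],
      toupper(m$atoms$element[i])))
  }
  adj <- adjacency(m)
  for (i in seq_len(n_atoms(m))) {
    if (length(adj[[i]]) == 0) next
    nb <- adj[[i]]
    while (length(nb) > 0) {
      take <- head(nb, 4)
      lines <- c(lines, paste0(sprintf("CONECT%5d", i),
                               paste0(sprintf("%5d", take), collapse = "")))
      nb <- nb[-seq_along(take)]
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## ---- XYZ ------------------------------------------------------------------

read_xyz <- function(path) {
  raw <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(raw[1])))
  if (is.na(n)) stop("XYZ parse error at line 1: atom count expected",
                     call. = FALSE)
  if (length(raw) < n + 2) stop("XYZ parse error: file truncated", call. = FALSE)
  comment <- raw[2]
  charge <- 0L
  cm <- regmatches(comment, regexpr("charge=(-?\\d+)", comment))
  if (length(cm) == 1) charge <- as.integer(sub("charge=", "", cm))
  flds <- strsplit(trimws(raw[3:(n + 2)]), "\\s+")
  bad <- which(lengths(flds) < 4)
  if (length(bad) > 0)
    stop("XYZ parse error at line ", bad[1] + 2, call. = FALSE)
  atoms <- data.frame(element = vapply(flds, `[[`, "", 1),
                      x = as.numeric(vapply(flds, `[[`, "", 2)),
                      y = as.numeric(vapply(flds, `[[`, "", 3)),
                      z = as.numeric(vapply(flds, `[[`, "", 4)),
                      formal_charge = 0L)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$formal_charges)) atoms$formal_charge <- as.integer(sc$formal_charges)
    if (!is.null(sc$partial_charges)) atoms$partial_charge <- as.numeric(sc$partial_charges)
  } else if (charge != 0L) {
    heavy <- which(atoms$element != "H")
    site <- if (length(heavy) > 0) heavy[1] else 1L
    atoms$formal_charge[site] <- charge
    warning("XYZ declares charge=", charge,
            " without a sidecar; formal charge placed on atom ", site)
  }
  bonds <- perceive_bonds(atoms)
  molecule(atoms, bonds, label = sub("\\.xyz$", "", basename(path),
                                     ignore.case = TRUE))
}

write_xyz <- function(m, path) {
  lines <- c(as.character(n_atoms(m)),
             sprintf("charge=%d %s", m$net_charge, m$label),
             sprintf("%-3s %14.6f %14.6f %14.6f", m$atoms$element,
                     m$atoms$x, m$atoms$y, m$atoms$z))
  writeLines(lines, path)
  if (any(m$atoms$formal_charge != 0L) || !all(is.na(m$atoms$partial_charge))) {
    jsonlite::write_json(
      list(formal_charges = m$atoms$formal_charge,
           partial_charges = m$atoms$partial_charge),
      paste0(path, ".json"), auto_unbox = FALSE, digits = NA, na = "null")
  }
  invisible(path)
}

## distance-based bond perception: bonded iff d < 1.3 (rcov_i + rcov_j)
perceive_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(NULL)
  rc <- element_row(atoms$element)$r_cov
  X <- as.matrix(atoms[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(X))
  thr <- 1.3 * outer(rc, rc, `+`)
  hit <- which(D < thr & upper.tri(D), arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  data.frame(a1 = hit[, 1], a2 = hit[, 2], order = 1L)
}
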