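## Secondary chemical shifts and a simple secondary-structure-propensity
## classification, for comparing states (decamer vs dimer) residue by
## residue. Random-coil reference shifts are consumed as an input table
## (e.g. from a neighbor-corrected predictor), never computed here.

#' Secondary chemical shifts (delta-delta CA - delta-delta CB)
#'
#' `Delta = (dCA - dCA_rc) - (dCB - dCB_rc)` per residue; sustained positive
#' runs indicate helix, negative runs strand. Glycines (no CB) and residues
#' missing a CB shift are scored on CA only and flagged.
#'
#' @param shifts data frame with columns `residue` (number), `restype`
#'   (one-letter code), `ca` and `cb` (ppm; `cb` may be `NA`)
#' @param random_coil data frame with columns `restype`, `ca`, `cb`
#'   (random-coil reference shifts per residue type)
#' @return data frame with `residue`, `restype`, `delta` (ppm), `flag`
#'   (`""` or `"ca_only"`)
#' @export
secondary_shift <- function(shifts, random_coil) {
  need <- c("residue", "restype", "ca")
  if (!all(need %in% names(shifts)))
    stop("shifts must have columns residue, restype, ca (and optionally cb)")
  if (!"cb" %in% names(shifts)) shifts$cb <- NA_real_
  idx <- match(shifts$restype, random_coil$restype)
  if (anyNA(idx)) {
    bad <- shifts$residue[is.na(idx)]
    stop("missing random-coil reference for residue(s) ",
         paste(bad, collapse = ", "))
  }
  rc_ca <- random_coil$ca[idx]
  rc_cb <- random_coil$cb[idx]
  d_ca <- shifts$ca - rc_ca
  d_cb <- shifts$cb - rc_cb
  ca_only <- is.na(shifts$cb) | is.na(rc_cb)
  delta <- ifelse(ca_only, d_ca, d_ca - d_cb)
  data.frame(residue = shifts$residue, restype = shifts$restype,
             delta = delta, flag = ifelse(ca_only, "ca_only", ""),
             stringsAsFactors = FALSE)
}

#' Classify secondary-structure segments from secondary shifts
#'
#' A residue run of at least `min_run` consecutive values above `+threshold`
#' is a helix segment; below `-threshold`, a strand segment; everything
#' else is coil. The +-0.7 ppm / run length 4 defaults are conventional.
#'
#' @param residues residue numbers (sorted; gaps allowed)
#' @param deltas secondary shifts (ppm), same length
#' @param threshold ppm threshold (default 0.7)
#' @param min_run minimal run length, >= 3
#' @return data frame of segments with columns `type` (`"helix"`/`"strand"`),
#'   `start`, `end`
#' @export
classify_sse <- function(residues, deltas, threshold = 0.7, min_run = 4) {
  if (min_run < 3) stop("min_run must be >= 3")
  stopifnot(length(residues) == length(deltas))
  ord <- order(residues)
  residues <- residues[ord]; deltas <- deltas[ord]
  state <- ifelse(is.na(deltas), 0L,
                  ifelse(deltas > threshold, 1L,
                         ifelse(deltas < -threshold, -1L, 0L)))
  ## breaks runs at sequence gaps
  contig <- c(TRUE, diff(residues) == 1L)
  segs <- list()
  i <- 1L
  n <- length(state)
  while (i <= n) {
    if (state[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && state[j + 1L] == state[i] && contig[j + 1L]) j <- j + 1L
    if (j - i + 1L >= min_run)
      segs[[length(segs) + 1L]] <-
        data.frame(type = if (state[i] > 0) "helix" else "strand",
                   start = residues[i], end = residues[j],
                   stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (length(segs) == 0)
    return(data.frame(type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

#' Read a chemical-shift loop from an NMR-STAR file
#'
#' Minimal reader for the `Atom_chem_shift` loop of NMR-STAR 3.x chemical
#' shift files: extracts residue number, residue type (three-letter,
#' converted to one-letter), atom name and shift value. Only the shift
#' loop is parsed; everything else in the file is ignored.
#'
#' @param path NMR-STAR file
#' @return data frame with columns `residue`, `restype`, `atom`, `shift`
#' @export
read_star_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ## locate loop whose tags belong to Atom_chem_shift
  starts <- grep("^\\s*loop_\\s*$", lines)
  for (s in starts) {
    i <- s + 1L
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    col <- function(name) match(paste0("_Atom_chem_shift.", name), tags)
    ic_res <- col("Seq_ID"); ic_typ <- col("Comp_ID")
    ic_atm <- col("Atom_ID"); ic_val <- col("Val")
    if (anyNA(c(ic_res, ic_typ, ic_atm, ic_val)))
      stop("shift loop lacks Seq_ID/Comp_ID/Atom_ID/Val tags")
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || ln == "stop_" || startsWith(ln, "#")) break
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) >= length(tags))
        rows[[length(rows) + 1L]] <-
          data.frame(residue = as.integer(f[ic_res]),
                     restype = aa3to1(f[ic_typ]),
                     atom = f[ic_atm],
                     shift = as.numeric(f[ic_val]),
                     stringsAsFactors = FALSE)
      i <- i + 1L
    }
    return(do.call(rbind, rows))
  }
  stop("no Atom_chem_shift loop found in ", path)
}

#' Arrange a long shift table into the wide CA/CB layout used by
#' [secondary_shift()]
#'
#' @param long data frame with columns `residue`, `restype`, `atom`, `shift`
#' @return data frame with columns `residue`, `restype`, `ca`, `cb`
#' @export
shifts_to_wide <- function(long) {
  res <- sort(unique(long$residue))
  pick <- function(r, a) {
    v <- long$shift[long$residue == r & toupper(long$atom) == a]
    if (length(v)) v[1] else NA_real_
  }
  data.frame(
    residue = res,
    restype = vapply(res, function(r) long$restype[long$residue == r][1], ""),
    ca = vapply(res, pick, numeric(1), a = "CA"),
    cb = vapply(res, pick, numeric(1), a = "CB"),
    stringsAsFactors = FALSE)
}

#' Three-letter to one-letter amino-acid codes
#' @param x character vector of three-letter codes (any case)
#' @return one-letter codes (`NA` for unknown)
#' @export
aa3to1 <- function(x) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  unname(map[toupper(x)])
}
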