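## Sequence-derived quantities (mass, extinction coefficient, expected
## amide counts) and structure-derived metrics (inter-residue distances
## across subunits, B-factor profiles, subunit-superposition RMSD).

## Average isotopic residue masses (Da), i.e. amino-acid mass minus water.
.residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.01528

#' Sequence record
#'
#' @param id identifier
#' @param seq one-letter residue string (20 standard residues)
#' @param tag_span optional integer vector of positions belonging to a
#'   purification tag
#' @return an object of class `sequence_record`
#' @export
sequence_record <- function(id, seq, tag_span = NULL) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) == 0) stop("empty sequence")
  letters1 <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(letters1), names(.residue_mass))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  structure(list(id = id, seq = seq, residues = letters1,
                 tag_span = tag_span),
            class = "sequence_record")
}

#' Read sequences from a FASTA file
#' @param path FASTA file
#' @return list of [sequence_record()]
#' @export
read_fasta_records <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  lapply(names(fa), function(nm) sequence_record(nm, as.character(fa[[nm]])))
}

#' The packaged synthetic stand-in peroxiredoxin sequence
#'
#' A synthetic 196-residue stand-in for the yeast peroxiredoxin chain (not
#' the database sequence): its composition was designed to match the
#' published aggregate properties of the protein -- 12 prolines (184
#' non-proline residues), cysteines at positions 47 and 170, two Trp, nine
#' Tyr (Pace extinction coefficient 24,535 M^-1 cm^-1 with the single
#' disulfide counted) and a ~21.6 kDa monomer (~216 kDa decamer).
#'
#' @return a [sequence_record()]
#' @export
tsa1_standin <- function() {
  read_fasta_records(system.file("extdata", "tsa1_standin_synthetic.fasta",
                                 package = "prxdyn", mustWork = TRUE))[[1]]
}

#' Molecular mass of a (multimeric) protein
#'
#' Average isotopic mass: sum of residue masses plus one water per chain,
#' times the multiplicity.
#'
#' @param seq a [sequence_record()]
#' @param multiplicity number of copies (10 for a decamer)
#' @return mass in kDa
#' @export
molecular_mass <- function(seq, multiplicity = 1) {
  stopifnot(inherits(seq, "sequence_record"))
  chain <- sum(.residue_mass[seq$residues]) + .water_mass
  multiplicity * chain / 1000
}

#' Theoretical molar extinction coefficient at 280 nm
#'
#' Pace convention: `eps = 5500 nTrp + 1490 nTyr + 125 n_cystine`
#' (M^-1 cm^-1).
#'
#' @param seq a [sequence_record()]
#' @param cystines number of disulfide bonds counted (must not exceed
#'   `floor(nCys / 2)`)
#' @return extinction coefficient in M^-1 cm^-1
#' @export
extinction_coefficient <- function(seq, cystines = 0) {
  stopifnot(inherits(seq, "sequence_record"))
  counts <- table(factor(seq$residues, levels = names(.residue_mass)))
  if (cystines > floor(counts[["C"]] / 2))
    stop("cystines exceeds floor(nCys/2)")
  5500 * counts[["W"]] + 1490 * counts[["Y"]] + 125 * cystines
}

#' Expected number of observable amide resonances
#'
#' Count of non-proline residues; the `"exclude-first"` convention also
#' drops the N-terminal residue, whose amide is never observed.
#'
#' @param seq a [sequence_record()]
#' @param convention `"all-nonproline"` (default) or `"exclude-first"`
#' @return integer count
#' @export
expected_amides <- function(seq, convention = c("all-nonproline",
                                                "exclude-first")) {
  stopifnot(inherits(seq, "sequence_record"))
  convention <- match.arg(convention)
  res <- seq$residues
  if (convention == "exclude-first") res <- res[-1]
  sum(res != "P")
}

#' Structure model from atom records
#'
#' A light container over an atom table; constructed from a data frame or
#' read from PDB/mmCIF via [read_structure()].
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`
#'   (three-letter), `elety` (atom name), `x`, `y`, `z` (Angstrom), `b`
#'   (B-factor), `occ` (occupancy)
#' @return an object of class `structure_model`
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z", "b", "occ")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns ", paste(need, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("coordinates must be finite")
  structure(list(atoms = atoms), class = "structure_model")
}

#' Read a structure from a PDB or mmCIF file
#'
#' First model only; for alternate locations the `A` (or blank) altloc is
#' kept.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file
#' @return a [structure_model()]
#' @export
read_structure <- function(path) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  structure_model(data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    b = if (is.null(at$b)) 0 else at$b,
    occ = if (is.null(at$o)) 1 else at$o,
    stringsAsFactors = FALSE))
}

## Select one atom; for atom = "gamma" resolves SG (Cys) / OG (Ser) / OG1
## (Thr) by residue type.
.pick_atom <- function(s, chain, resno, atom) {
  at <- s$atoms[s$atoms$chain == chain & s$atoms$resno == resno, ]
  if (nrow(at) == 0)
    stop("no atoms for chain ", chain, " residue ", resno)
  if (identical(atom, "gamma")) {
    atom <- switch(at$resid[1],
                   CYS = "SG", SER = "OG", THR = "OG1",
                   stop("no gamma convention for residue type ", at$resid[1]))
  }
  hit <- at[at$elety == atom, ]
  if (nrow(hit) == 0)
    stop("atom ", atom, " not found in chain ", chain, " residue ", resno)
  as.numeric(hit[1, c("x", "y", "z")])
}

#' Distance between two atoms
#'
#' Euclidean distance between selections `(chain, residue, atom)`. The
#' atom name `"gamma"` resolves to the side-chain gamma atom by residue
#' type (SG for Cys, OG for Ser), which makes the peroxidatic-site
#' selection independent of whether position 47 is the wild-type Cys or the
#' C47S reduced-mimic Ser.
#'
#' @param s a [structure_model()]
#' @param sel_a,sel_b lists `list(chain=, resno=, atom=)`
#' @return distance in Angstrom
#' @export
inter_residue_distance <- function(s, sel_a, sel_b) {
  stopifnot(inherits(s, "structure_model"))
  pa <- .pick_atom(s, sel_a$chain, sel_a$resno, sel_a$atom)
  pb <- .pick_atom(s, sel_b$chain, sel_b$resno, sel_b$atom)
  sqrt(sum((pa - pb)^2))
}

#' Per-residue backbone B-factor profile
#'
#' Mean B-factor over backbone atoms (N, CA, C, O) per residue and chain,
#' plus the across-chain mean and range per residue number.
#'
#' @param s a [structure_model()]
#' @return list with `per_chain` (data frame chain/resno/b) and `summary`
#'   (data frame resno/b_mean/b_min/b_max); flags all-zero B columns via
#'   attribute `zero_b`
#' @export
bfactor_profile <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  bb <- s$atoms[s$atoms$elety %in% c("N", "CA", "C", "O"), ]
  if (nrow(bb) == 0) stop("no backbone atoms present")
  per <- stats::aggregate(b ~ chain + resno, data = bb, FUN = mean)
  smry <- do.call(rbind, lapply(split(per, per$resno), function(d)
    data.frame(resno = d$resno[1], b_mean = mean(d$b),
               b_min = min(d$b), b_max = max(d$b))))
  smry <- smry[order(smry$resno), ]
  rownames(smry) <- NULL
  out <- list(per_chain = per, summary = smry)
  attr(out, "zero_b") <- all(bb$b == 0)
  out
}

#' Pairwise backbone superposition RMSD between chains
#'
#' Optimal rigid-body (Kabsch) superposition of every chain pair on their
#' common backbone atoms; the intersection of residue numbers is used and
#' reported.
#'
#' @param s a [structure_model()]
#' @param chains chain identifiers (default: all); >= 2 required
#' @param atom_set atom names used for the fit (backbone by default)
#' @return symmetric RMSD matrix (Angstrom) with attribute
#'   `common_residues`
#' @export
superpose_rmsd <- function(s, chains = NULL,
                           atom_set = c("N", "CA", "C", "O")) {
  stopifnot(inherits(s, "structure_model"))
  if (is.null(chains)) chains <- unique(s$atoms$chain)
  if (length(chains) < 2) stop("need >= 2 chains")
  sel <- s$atoms[s$atoms$chain %in% chains & s$atoms$elety %in% atom_set, ]
  common <- Reduce(intersect, lapply(chains, function(ch)
    unique(sel$resno[sel$chain == ch])))
  if (length(common) * length(atom_set) < 3)
    stop("fewer than 3 common atoms between chains")
  coords <- lapply(chains, function(ch) {
    d <- sel[sel$chain == ch & sel$resno %in% common, ]
    d <- d[order(d$resno, match(d$elety, atom_set)), ]
    as.numeric(t(as.matrix(d[, c("x", "y", "z")])))
  })
  n <- length(chains)
  rmat <- matrix(0, n, n, dimnames = list(chains, chains))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ## fit.xyz notes that all positions are used when no indices are given;
    ## that is exactly the intent here
    fitted <- suppressWarnings(
      bio3d::fit.xyz(fixed = coords[[i]], mobile = coords[[j]]))
    rmat[i, j] <- rmat[j, i] <- bio3d::rmsd(coords[[i]], fitted)
  }
  attr(rmat, "common_residues") <- common
  rmat
}
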