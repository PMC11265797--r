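#' Residue group selection
#'
#' Selects atoms by residue-number intervals plus an atom-name filter
#' (default CA, i.e. alpha carbons). Intervals are inclusive.
#'
#' @param label group label
#' @param ranges two-column matrix (lo, hi) of inclusive residue intervals,
#'   or a vector c(lo, hi) for a single interval
#' @param atom_filter atom name to keep; `"*"` keeps all atoms
#' @export
residue_group <- function(label, ranges, atom_filter = "CA") {
  ranges <- rbind(ranges)
  stopifnot(ncol(ranges) == 2)
  if (any(ranges[, 1] > ranges[, 2]))
    stop("residue_group: interval with lo > hi in group '", label, "'")
  structure(list(label = label, ranges = ranges, atom_filter = atom_filter),
            class = "residue_group")
}

#' Residue numbers covered by a group
#' @param group a [residue_group()]
#' @return sorted unique residue numbers
#' @export
group_residues <- function(group) {
  sort(unique(unlist(apply(group$ranges, 1, function(r) r[1]:r[2], simplify = FALSE))))
}

#' Gate collective-variable definition
#'
#' An inter-bundle centre-of-mass distance: the CV value is the Euclidean
#' distance between the COM of group A (N-terminal bundle selection) and the
#' COM of group B (C-terminal bundle selection).
#'
#' @param name CV name ("tip", "base" or custom)
#' @param group_a,group_b [residue_group()]s for the two bundles
#' @param check_disjoint verify that the groups share no residues
#' @export
gate_cv_definition <- function(name, group_a, group_b, check_disjoint = TRUE) {
  stopifnot(inherits(group_a, "residue_group"), inherits(group_b, "residue_group"))
  if (check_disjoint &&
      length(intersect(group_residues(group_a), group_residues(group_b))))
    stop("gate_cv_definition: groups A and B overlap")
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "gate_cv_definition")
}

#' Built-in tip and base gate CVs
#'
#' The canonical extracellular (tip) and intracellular (base) gate CVs for
#' the PepT2 transporter: centre-of-mass distances between the Calpha atoms of
#' the helical tip / base segments of the N- and C-terminal six-helix bundles.
#' Each bundle selection is six 12-residue intervals (72 residues per group).
#' Within a bundle the tip and base selections of the two *different* CVs may
#' overlap (120-121 and 227-228 appear in both N-bundle tips and bases); the
#' two groups of any one CV are disjoint.
#'
#' @return list with elements `tip` and `base`, each a [gate_cv_definition()]
#' @export
builtin_gate_cvs <- function() {
  n_tips <- rbind(c(63, 74), c(79, 90), c(120, 131), c(143, 154),
                  c(194, 205), c(217, 228))
  n_bases <- rbind(c(46, 57), c(93, 104), c(110, 121), c(161, 172),
                   c(177, 188), c(227, 238))
  c_tips <- rbind(c(320, 331), c(341, 352), c(392, 403), c(609, 620),
                  c(655, 666), c(671, 682))
  c_bases <- rbind(c(290, 301), c(359, 370), c(376, 387), c(626, 637),
                   c(642, 653), c(686, 697))
  list(
    tip = gate_cv_definition("tip",
      residue_group("N-bundle tips", n_tips),
      residue_group("C-bundle tips", c_tips)),
    base = gate_cv_definition("base",
      residue_group("N-bundle bases", n_bases),
      residue_group("C-bundle bases", c_bases))
  )
}

.select_atoms <- function(frame, group) {
  keep <- frame$resid %in% group_residues(group)
  if (group$atom_filter != "*") keep <- keep & frame$name == group$atom_filter
  frame[keep, , drop = FALSE]
}

#' Mass-weighted centre of mass of a residue group
#'
#' @param frame a `structure_frame`
#' @param group a [residue_group()]
#' @return 3-vector (nm)
#' @export
center_of_mass <- function(frame, group) {
  sel <- .select_atoms(frame, group)
  if (nrow(sel) == 0L) {
    missing <- setdiff(group_residues(group), frame$resid)
    stop("center_of_mass: empty selection for group '", group$label, "'",
         if (length(missing)) paste0("; residues absent from frame: ",
                                     paste(utils::head(missing, 10), collapse = ", ")))
  }
  w <- sel$mass / sum(sel$mass)
  c(sum(w * sel$x), sum(w * sel$y), sum(w * sel$z))
}

#' Evaluate a gate CV on one frame
#'
#' @param frame a `structure_frame`
#' @param definition a [gate_cv_definition()]
#' @return inter-group COM distance, nm
#' @export
gate_cv <- function(frame, definition) {
  stopifnot(inherits(definition, "gate_cv_definition"))
  a <- center_of_mass(frame, definition$group_a)
  b <- center_of_mass(frame, definition$group_b)
  sqrt(sum((a - b)^2))
}

#' Evaluate a gate CV over a frame sequence
#'
#' @param frames list of `structure_frame`s
#' @param definition a [gate_cv_definition()]
#' @param times optional time stamps (ps); defaults to 1..n
#' @return a [cv_series()] with one column named after the CV
#' @export
gate_cv_series <- function(frames, definition, times = NULL) {
  vals <- vapply(frames, gate_cv, 0, definition = definition)
  if (is.null(times)) times <- seq_along(vals)
  cv_series(definition$name, times, matrix(vals, ncol = 1))
}

#' Contact specification between two selections
#'
#' @param selection_a,selection_b [residue_group()]s
#' @param cutoff contact distance cutoff, nm. The default 0.4 nm is a common
#'   salt-bridge criterion between polar heavy atoms.
#' @export
contact_spec <- function(selection_a, selection_b, cutoff = 0.4) {
  stopifnot(cutoff > 0)
  structure(list(a = selection_a, b = selection_b, cutoff = cutoff),
            class = "contact_spec")
}

#' Fraction of frames in which a contact is formed
#'
#' A frame is "in contact" when the minimum distance between any atom of
#' selection A and any atom of selection B is at most the cutoff.
#'
#' @param frames list of `structure_frame`s
#' @param spec a [contact_spec()]
#' @return fraction in [0, 1]
#' @export
contact_fraction <- function(frames, spec) {
  stopifnot(inherits(spec, "contact_spec"), length(frames) >= 1L)
  formed <- vapply(frames, function(fr) {
    a <- .select_atoms(fr, spec$a)
    b <- .select_atoms(fr, spec$b)
    if (nrow(a) == 0L || nrow(b) == 0L)
      stop("contact_fraction: empty selection ('", spec$a$label, "' / '",
           spec$b$label, "')")
    pa <- as.matrix(a[, c("x", "y", "z")])
    pb <- as.matrix(b[, c("x", "y", "z")])
    d2min <- min(outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb))
    sqrt(max(d2min, 0)) <= spec$cutoff
  }, NA)
  mean(formed)
}

#' Build a synthetic structure frame from raw coordinates
#'
#' Test/fixture helper: makes a valid `structure_frame` of CA atoms at given
#' positions and residue numbers.
#'
#' @param positions matrix (n x 3) of positions in nm
#' @param resid residue numbers (default 1..n)
#' @param name atom names (default "CA")
#' @param element element symbols (default "C")
#' @param mass atomic masses (default carbon)
#' @export
synthetic_frame <- function(positions, resid = NULL, name = "CA",
                            element = "C", mass = 12.011) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (is.null(resid)) resid <- seq_len(n)
  validate_structure_frame(data.frame(
    serial = seq_len(n), name = rep_len(name, n), resid = resid,
    chain = "A", element = rep_len(element, n), mass = rep_len(mass, n),
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    stringsAsFactors = FALSE))
}
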