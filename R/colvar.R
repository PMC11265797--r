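#' Collective-variable time series
#'
#' A `cv_series` holds time-stamped values of one or more collective variables
#' (CVs) for a single simulation window or run: a strictly increasing time axis
#' (ps) and one column of values per CV. Gate CVs are in nm; principal-component
#' projections are in the (arbitrary) units of the underlying coordinates.
#'
#' @param labels character vector of CV names (time is not a label)
#' @param times numeric vector of times in ps, strictly increasing
#' @param values numeric matrix, one row per time point, one column per label
#' @return an object of class `cv_series`
#' @export
cv_series <- function(labels, times, values) {
  labels <- as.character(labels)
  times <- as.numeric(times)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(labels) == 0L) stop("cv_series: at least one CV label required")
  if (anyDuplicated(labels)) stop("cv_series: duplicate CV labels")
  if (length(times) == 0L) stop("cv_series: no samples")
  if (nrow(values) != length(times))
    stop("cv_series: row count (", nrow(values), ") does not match time count (",
         length(times), ")")
  if (ncol(values) != length(labels))
    stop("cv_series: column count does not match label count")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("cv_series: times must be finite and strictly increasing")
  colnames(values) <- labels
  structure(list(labels = labels, times = times, values = values),
            class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat("<cv_series> ", length(x$times), " samples, ",
      length(x$labels), " CV(s): ", paste(x$labels, collapse = ", "), "\n",
      "  time range ", x$times[1], " .. ", x$times[length(x$times)], " ps\n",
      sep = "")
  invisible(x)
}

#' Number of samples in a cv_series
#' @param series a [cv_series()]
#' @export
n_samples <- function(series) length(series$times)

#' Read a PLUMED-style COLVAR table
#'
#' The reader is schema-driven: the first non-blank line must be a header of
#' the form `#! FIELDS time <cv1> <cv2> ...`; subsequent comment lines starting
#' with `#` are skipped, and the remaining lines are whitespace-separated
#' numeric rows. The first column is the time axis.
#'
#' @param path path to a COLVAR-format text file
#' @return a [cv_series()]
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop("read_colvar: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("read_colvar: empty file: ", path)
  header <- lines[[1]]
  if (!startsWith(trimws(header), "#! FIELDS"))
    stop("read_colvar: missing '#! FIELDS' header in ", path)
  fields <- strsplit(trimws(header), "\\s+")[[1]][-(1:2)]
  if (length(fields) < 2L || fields[1] != "time")
    stop("read_colvar: header must name 'time' plus at least one CV field")
  data_lines <- lines[-1]
  data_lines <- data_lines[!startsWith(trimws(data_lines), "#")]
  if (length(data_lines) == 0L) stop("read_colvar: no samples in ", path)
  tokens <- strsplit(trimws(data_lines), "\\s+")
  ncols <- length(fields)
  bad <- which(vapply(tokens, length, 1L) != ncols)
  if (length(bad))
    stop("read_colvar: line ", bad[1] + 1L, " has ", length(tokens[[bad[1]]]),
         " fields, expected ", ncols)
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(tokens)), ncol = ncols, byrow = TRUE))
  if (anyNA(mat)) {
    row <- which(apply(is.na(mat), 1, any))[1]
    stop("read_colvar: malformed numeric token on data line ", row)
  }
  cv_series(labels = fields[-1], times = mat[, 1], values = mat[, -1, drop = FALSE])
}

#' Write a cv_series as a COLVAR table
#'
#' Emits a `#! FIELDS` header plus rows in fixed-width scientific notation with
#' enough digits that `read_colvar(write_colvar(x))` round-trips to better than
#' 1e-9 relative.
#'
#' @param series a [cv_series()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_colvar <- function(series, path) {
  stopifnot(inherits(series, "cv_series"))
  if (any(grepl("\\s", series$labels)))
    stop("write_colvar: CV labels must not contain whitespace")
  header <- paste("#! FIELDS time", paste(series$labels, collapse = " "))
  mat <- cbind(series$times, series$values)
  rows <- apply(mat, 1, function(r) paste(sprintf("% .12e", r), collapse = " "))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("write_colvar: cannot open ", path, " for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

# atomic masses (amu) by element symbol, protein/ligand staples only
.ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.990, K = 39.098,
  CL = 35.45, CA = 40.078, MN = 54.938
)

.element_from_atom_name <- function(name) {
  # strip digits/primes; first letter(s) give the element for PDB protein atoms
  core <- gsub("[0-9'\"]", "", toupper(trimws(name)))
  if (nchar(core) == 0L) return(NA_character_)
  substr(core, 1, 1)
}

#' Read a PDB coordinate file into a structure frame
#'
#' Parses ATOM/HETATM records through bio3d, converts coordinates from
#' Angstrom to nm, and assigns per-atom masses from the element symbol
#' (falling back to the first character of the atom name).
#'
#' @param path path to a PDB file
#' @return a `structure_frame`: data.frame with columns serial, name, resid,
#'   chain, element, mass (amu), and x, y, z (nm)
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop("read_structure: not parseable as PDB: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("read_structure: no ATOM records in ", path)
  element <- toupper(trimws(a$elesy))
  missing_el <- is.na(element) | !nzchar(element)
  element[missing_el] <- vapply(a$elety[missing_el], .element_from_atom_name, "")
  mass <- .ELEMENT_MASSES[element]
  if (anyNA(mass))
    stop("read_structure: unknown element(s): ",
         paste(unique(element[is.na(mass)]), collapse = ", "))
  frame <- data.frame(
    serial = as.integer(a$eleno), name = trimws(a$elety),
    resid = as.integer(a$resno), chain = as.character(a$chain),
    element = element, mass = as.numeric(mass),
    x = a$x / 10, y = a$y / 10, z = a$z / 10,
    stringsAsFactors = FALSE
  )
  validate_structure_frame(frame)
}

#' Construct/validate a structure frame from raw fields
#'
#' @param frame data.frame with columns serial, name, resid, chain, element,
#'   mass, x, y, z (positions in nm)
#' @return the validated frame with class `structure_frame`
#' @export
validate_structure_frame <- function(frame) {
  need <- c("serial", "name", "resid", "chain", "element", "mass", "x", "y", "z")
  if (!all(need %in% names(frame)))
    stop("structure_frame: missing columns: ",
         paste(setdiff(need, names(frame)), collapse = ", "))
  if (anyDuplicated(frame$serial))
    stop("structure_frame: duplicate atom serials")
  if (!all(is.finite(frame$x)) || !all(is.finite(frame$y)) || !all(is.finite(frame$z)))
    stop("structure_frame: non-finite coordinates")
  class(frame) <- c("structure_frame", "data.frame")
  frame
}

#' Campaign plan for sampling bookkeeping
#'
#' A campaign plan is a set of blocks, each describing
#' `n_conditions x n_replicates x n_windows` runs with given per-window
#' durations (ns). It carries the arithmetic behind published sampling totals.
#'
#' @param name campaign label
#' @param blocks list of blocks; each block is a list with `label`,
#'   `n_conditions`, `n_replicates`, `n_windows` and `durations_ns`
#'   (numeric vector; recycled per window if length 1)
#' @return a `campaign_plan`
#' @export
campaign_plan <- function(name, blocks) {
  stopifnot(is.character(name), length(name) == 1L, is.list(blocks), length(blocks) >= 1L)
  blocks <- lapply(blocks, function(b) {
    for (f in c("label", "n_conditions", "n_replicates", "n_windows", "durations_ns"))
      if (is.null(b[[f]])) stop("campaign_plan: block missing field '", f, "'")
    counts <- c(b$n_conditions, b$n_replicates, b$n_windows)
    if (any(counts < 1) || any(counts != round(counts)))
      stop("campaign_plan: counts must be integers >= 1 in block '", b$label, "'")
    if (length(b$durations_ns) == 0L)
      stop("campaign_plan: empty duration list in block '", b$label, "'")
    if (any(b$durations_ns <= 0))
      stop("campaign_plan: durations must be > 0 in block '", b$label, "'")
    b
  })
  structure(list(name = name, blocks = blocks), class = "campaign_plan")
}

#' Total production sampling of a campaign, in microseconds
#'
#' Per block the total is
#' `n_conditions * n_replicates * n_windows * sum(durations_ns)`, converted
#' ns to microseconds and summed over blocks. `rounding = "nearest_us"`
#' reproduces integer-microsecond claims; `"one_decimal_us"` reproduces totals
#' printed with one decimal.
#'
#' @param plan a [campaign_plan()]
#' @param rounding one of "none", "nearest_us", "one_decimal_us"
#' @return total sampling in microseconds
#' @export
campaign_total_time <- function(plan, rounding = c("none", "nearest_us", "one_decimal_us")) {
  stopifnot(inherits(plan, "campaign_plan"))
  rounding <- match.arg(rounding)
  per_block <- vapply(plan$blocks, function(b)
    b$n_conditions * b$n_replicates * b$n_windows * sum(b$durations_ns), 0)
  total_us <- sum(per_block) / 1000
  switch(rounding,
         none = total_us,
         nearest_us = round(total_us),
         one_decimal_us = round(total_us, 1))
}

#' Per-block sampling inventory table
#'
#' @param plan a [campaign_plan()]
#' @return data.frame with one row per block (microseconds) plus totals
#' @export
campaign_inventory <- function(plan) {
  stopifnot(inherits(plan, "campaign_plan"))
  data.frame(
    block = vapply(plan$blocks, `[[`, "", "label"),
    n_runs = vapply(plan$blocks, function(b)
      b$n_conditions * b$n_replicates * b$n_windows, 0),
    total_us = vapply(plan$blocks, function(b)
      b$n_conditions * b$n_replicates * b$n_windows * sum(b$durations_ns) / 1000, 0),
    stringsAsFactors = FALSE
  )
}

#' Read a campaign plan from a YAML config
#'
#' Expected layout: `name:` plus a `blocks:` list whose entries carry `label`,
#' `n_conditions`, `n_replicates`, `n_windows`, `durations_ns`.
#'
#' @param path path to a YAML file
#' @return a [campaign_plan()]
#' @export
read_campaign_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$blocks))
    stop("read_campaign_yaml: config must contain 'name' and 'blocks'")
  campaign_plan(cfg$name, cfg$blocks)
}
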