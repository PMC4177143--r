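#' Reference ranges for panel analytes
#'
#' A reference range is the clinical NORMAL interval of an analyte. Ranges
#' drive both encodings used in the package: the affine normalization that
#' maps the interval onto `[-1, 1]` (used by the SN derivative machinery)
#' and the LOW/NORMAL/HIGH discretization (used by the association miner).
#'
#' @param parameter character vector of analyte names (lower-case tokens
#'   matching cohort column names, e.g. `"creatinine"`).
#' @param low,high numeric vectors of interval bounds in clinical units;
#'   `low < high`, both finite.
#' @param units character vector of unit labels.
#' @return `data.frame` with columns `parameter`, `low`, `high`, `units`.
#' @examples
#' referenceRanges("creatinine", 0.6, 1.2, "mg/dL")
#' @export
referenceRanges <- function(parameter, low, high, units = NA_character_) {
  stopifnot(length(parameter) == length(low), length(low) == length(high))
  low <- as.numeric(low); high <- as.numeric(high)
  if (any(!is.finite(low)) || any(!is.finite(high)))
    snConfigError("reference range bounds must be finite")
  if (any(low >= high))
    snConfigError("reference ranges require low < high for every parameter")
  if (anyDuplicated(parameter))
    snConfigError("duplicate parameter in reference ranges")
  data.frame(parameter = as.character(parameter), low = low, high = high,
             units = rep_len(as.character(units), length(parameter)),
             stringsAsFactors = FALSE)
}

#' Built-in default reference ranges
#'
#' Conventional adult reference intervals for the five analytes the package
#' works with. These are implementation defaults chosen from standard
#' clinical practice; any study should supply its own laboratory's ranges
#' via [readRanges()] or [referenceRanges()].
#'
#' @return `data.frame` in the [referenceRanges()] layout.
#' @examples
#' defaultRanges()
#' @export
defaultRanges <- function() {
  referenceRanges(
    parameter = c("creatinine", "bun", "sgot", "sgpt", "haemoglobin"),
    low   = c(0.6,  7,  8,  7, 12),
    high  = c(1.2, 20, 45, 56, 17),
    units = c("mg/dL", "mg/dL", "U/L", "U/L", "g/dL")
  )
}

#' Read reference ranges from a YAML configuration file
#'
#' The file must contain a top-level `ranges:` mapping from parameter name
#' to a `low`/`high` (and optionally `units`) block.
#'
#' @param path path to a YAML file.
#' @return `data.frame` in the [referenceRanges()] layout.
#' @export
readRanges <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$ranges))
    snConfigError(sprintf("no 'ranges:' block in %s", path))
  nm <- names(cfg$ranges)
  lo <- vapply(cfg$ranges, function(r) as.numeric(r$low), numeric(1))
  hi <- vapply(cfg$ranges, function(r) as.numeric(r$high), numeric(1))
  un <- vapply(cfg$ranges, function(r)
    if (is.null(r$units)) NA_character_ else as.character(r$units),
    character(1))
  referenceRanges(nm, lo, hi, un)
}

#' Write reference ranges to a YAML configuration file
#'
#' @param ranges `data.frame` in the [referenceRanges()] layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRanges <- function(ranges, path) {
  blocks <- lapply(seq_len(nrow(ranges)), function(i)
    list(low = ranges$low[i], high = ranges$high[i], units = ranges$units[i]))
  names(blocks) <- ranges$parameter
  yaml::write_yaml(list(ranges = blocks), path)
  invisible(path)
}

.rangeRow <- function(ranges, parameter) {
  i <- match(parameter, ranges$parameter)
  if (is.na(i))
    snConfigError(sprintf("no reference range for parameter '%s'", parameter))
  ranges[i, , drop = FALSE]
}

#' Normalize a panel onto reference-range units
#'
#' Each analyte value `v` with reference interval `(low, high)` maps to
#' `(v - mid) / halfwidth` where `mid = (low + high)/2` and
#' `halfwidth = (high - low)/2`. Values inside the reference interval land
#' in `[-1, 1]`; the midpoint maps to 0. The map is affine and strictly
#' increasing per parameter.
#'
#' @param panel named numeric vector (or one-row data.frame) of analyte
#'   values in clinical units.
#' @param ranges reference ranges covering every panel parameter.
#' @return named numeric vector of normalized values, same order as `panel`.
#' @examples
#' normalizePanel(c(creatinine = 1.8), defaultRanges())  # (1.8-0.9)/0.3 = 3
#' @export
normalizePanel <- function(panel, ranges) {
  if (is.data.frame(panel)) panel <- unlist(panel[1, , drop = TRUE])
  if (is.null(names(panel)) || anyNA(names(panel)))
    snConfigError("panel values must be named by parameter")
  out <- vapply(names(panel), function(p) {
    r <- .rangeRow(ranges, p)
    mid <- (r$low + r$high) / 2
    hw <- (r$high - r$low) / 2
    (panel[[p]] - mid) / hw
  }, numeric(1))
  names(out) <- names(panel)
  out
}

#' Discretize a panel into LOW / NORMAL / HIGH categories
#'
#' Values strictly below the reference interval are LOW, strictly above are
#' HIGH, and boundary values are NORMAL (closed-interval convention,
#' matching the clinical reading of "within range"). Consistent with
#' [normalizePanel()]: HIGH iff the normalized value exceeds 1, LOW iff it
#' is below -1.
#'
#' @inheritParams normalizePanel
#' @return named character vector with values in `{"LOW","NORMAL","HIGH"}`.
#' @examples
#' discretizePanel(c(creatinine = 1.8, bun = 15), defaultRanges())
#' @export
discretizePanel <- function(panel, ranges) {
  if (is.data.frame(panel)) panel <- unlist(panel[1, , drop = TRUE])
  if (is.null(names(panel)) || anyNA(names(panel)))
    snConfigError("panel values must be named by parameter")
  # compared on the raw clinical values so interval endpoints are exactly
  # NORMAL (no float slack from the affine rescaling)
  out <- vapply(names(panel), function(p) {
    r <- .rangeRow(ranges, p)
    v <- panel[[p]]
    if (v > r$high) "HIGH" else if (v < r$low) "LOW" else "NORMAL"
  }, character(1))
  names(out) <- names(panel)
  out
}

# Item-token spelling used in the mined rule tables: kidney-panel analytes
# carry the KFT_ prefix, liver-panel the LFT_ prefix, haemoglobin its
# conventional label, and the disease state is STATE=<s>.
.itemPrefixes <- c(
  creatinine = "KFT_Creatinine", bun = "KFT_BUN",
  sgot = "LFT_SGOT", sgpt = "LFT_SGPT",
  haemoglobin = "Haemoglobin_content"
)

#' Item token for a discretized analyte or a disease state
#'
#' @param parameter analyte name (e.g. `"creatinine"`) or `"state"`.
#' @param value category (`"LOW"`, `"NORMAL"`, `"HIGH"`) or integer state.
#' @return character token such as `"KFT_Creatinine=HIGH"` or `"STATE=1"`.
#' @examples
#' itemToken("creatinine", "HIGH")
#' itemToken("state", 1)
#' @export
itemToken <- function(parameter, value) {
  if (identical(parameter, "state")) return(paste0("STATE=", value))
  label <- .itemPrefixes[parameter]
  label[is.na(label)] <- parameter[is.na(label)]
  paste0(label, "=", value)
}
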