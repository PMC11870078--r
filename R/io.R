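#' Write a breath series as delimited text
#'
#' One row per respiratory cycle with columns `cycle`, `value`, `is_sigh`
#' and (when labelled) `phase`, preceded by a provenance comment line
#' recording the package version, the seed and a hash of the resolved
#' configuration.
#'
#' @param series A [breath_series()].
#' @param path Output file path.
#' @param seed Seed to record in the provenance line (optional).
#' @param config Arbitrary configuration object to hash into the
#'   provenance line (optional).
#' @return `path`, invisibly.
#' @export
write_breath_csv <- function(series, path, seed = NULL, config = NULL) {
  stopifnot(inherits(series, "breath_series"))
  d <- as.data.frame(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(seed, config), con)
  utils::write.table(d, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

provenance_line <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("breathvar"))
  sprintf("# breathvar %s; seed=%s; config=%s", ver,
          if (is.null(seed)) "NA" else format(seed),
          config_hash(config))
}

# FNV-1a hash of the deparsed config, for provenance lines; file paths are
# excluded so the same run written to a different location hashes the same
config_hash <- function(config) {
  if (is.list(config))
    config <- config[setdiff(names(config), c("out", "in", "residuals"))]
  s <- paste(deparse(config), collapse = " ")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (as.double(h) * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

#' Read a breath-by-breath CPET export
#'
#' Reads delimited text with one row per respiratory cycle and a header
#' row. The delimiter is auto-detected among comma, semicolon and tab
#' (European CPET software commonly emits semicolon-delimited files with
#' decimal commas, which are normalised to points). Lines starting with
#' `#` are ignored. The selected parameter column is `vt_ml`/`vt`/`value`
#' for tidal volume or `bf_per_min`/`bf`/`value` for breathing frequency;
#' units are fixed to mL and breaths/min (no litre conversion — a VT
#' column whose median is below 15 triggers a units warning). A `phase`
#' column becomes per-cycle phase labels; a truthy `is_sigh` column
#' becomes sigh positions. Cycle indices are 1-based and must be strictly
#' increasing.
#'
#' @param path Path to the delimited text file.
#' @param parameter `"vt"` or `"bf"` — which parameter column to read.
#' @return A [breath_series()].
#' @export
read_breath_csv <- function(path, parameter = c("vt", "bf")) {
  parameter <- match.arg(parameter)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("format error in ", path, ": no header row found")
  line_no <- which(keep)
  body <- lines[keep]

  header <- body[1L]
  counts <- vapply(c(",", ";", "\t"),
                   function(s) lengths(regmatches(header,
                                                  gregexpr(s, header,
                                                           fixed = TRUE))),
                   integer(1))
  if (max(counts) == 0L)
    stop("format error at line ", line_no[1L],
         ": header has a single column; expected cycle plus a value column")
  delim <- c(",", ";", "\t")[which.max(counts)]

  d <- utils::read.table(text = body, sep = delim, header = TRUE,
                         colClasses = "character", strip.white = TRUE)
  names(d) <- tolower(trimws(names(d)))
  to_num <- function(x) suppressWarnings(as.numeric(gsub(",", ".", x,
                                                         fixed = TRUE)))

  if (!"cycle" %in% names(d))
    stop("format error at line ", line_no[1L], ": no 'cycle' column")
  cycle <- to_num(d$cycle)
  if (any(is.na(cycle)))
    stop("format error at line ",
         line_no[1L + which(is.na(cycle))[1L]], ": non-numeric cycle")
  if (any(diff(cycle) <= 0))
    stop("format error at line ",
         line_no[1L + which(diff(cycle) <= 0)[1L] + 1L],
         ": cycle indices must be strictly increasing")

  cand <- switch(parameter, vt = c("vt_ml", "vt", "value"),
                 bf = c("bf_per_min", "bf", "value"))
  col <- cand[cand %in% names(d)][1L]
  if (is.na(col))
    stop("format error: no ", toupper(parameter), " column among ",
         paste(cand, collapse = "/"))
  v <- to_num(d[[col]])
  if (any(is.na(v))) {
    bad <- which(is.na(v))
    stop("format error: missing/non-numeric ", col, " values at line(s) ",
         paste(line_no[1L + bad], collapse = ", "))
  }
  if (!length(v)) stop("format error: empty selection for ", col)
  if (parameter == "vt" && stats::median(v) < 15)
    warning("VT median below 15; values may be in litres, expected mL")

  phase <- if ("phase" %in% names(d)) d$phase else NULL
  sighs <- if ("is_sigh" %in% names(d)) {
    flag <- tolower(d$is_sigh) %in% c("true", "t", "1", "yes")
    if (any(flag)) which(flag) else NULL
  } else NULL
  breath_series(v, parameter = parameter, phase = phase,
                sigh_positions = sighs)
}
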