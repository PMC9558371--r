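#' Paired forward/reverse work samples for one alchemical transformation
#'
#' A `work_set` bundles the work values (kJ/mol) measured along fast
#' "forward" (wild type to mutant) and "reverse" (mutant to wild type)
#' alchemical transitions with the simulation temperature.  It is the input
#' to every free-energy estimator in the package.
#'
#' @param forward Numeric vector of forward work values, kJ/mol (>= 1 value).
#' @param reverse Numeric vector of reverse work values, kJ/mol (>= 1 value).
#' @param temperature Temperature in kelvin (default 310, body temperature,
#'   the condition the bundled KIT analysis assumes).
#' @param transformation_id Label identifying the transformation, typically
#'   `mutation x state x leg` (e.g. `"D816V_active_folded"`).
#' @param dg_true Optional known ground-truth free-energy difference, kJ/mol.
#'   Only populated by the synthetic generator; used by test oracles, never
#'   by the estimators.
#' @return An object of class `work_set`.
#' @seealso [bar_estimate()], [crooks_crossing_estimate()],
#'   [generate_cft_work_samples()]
#' @export
work_set <- function(forward, reverse, temperature = 310,
                     transformation_id = "", dg_true = NA_real_) {
  forward <- as.numeric(forward)
  reverse <- as.numeric(reverse)
  if (length(forward) < 1L || length(reverse) < 1L)
    stop("a work_set needs at least one work value in each direction", call. = FALSE)
  if (anyNA(forward) || anyNA(reverse))
    stop("work values must not contain NA", call. = FALSE)
  beta <- beta_from_temperature(temperature)  # validates temperature
  structure(
    list(forward = forward, reverse = reverse,
         temperature = as.numeric(temperature), beta = beta,
         transformation_id = as.character(transformation_id)[1L],
         dg_true = as.numeric(dg_true)[1L]),
    class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("work_set '%s': %d forward / %d reverse transitions at %g K\n",
              x$transformation_id, length(x$forward), length(x$reverse),
              x$temperature))
  cat(sprintf("  forward work: mean %.3f sd %.3f kJ/mol\n",
              mean(x$forward), stats::sd(x$forward)))
  cat(sprintf("  reverse work: mean %.3f sd %.3f kJ/mol\n",
              mean(x$reverse), stats::sd(x$reverse)))
  invisible(x)
}

#' Write work sets to the tabular work format
#'
#' One row per transition, tab-separated, with header columns
#' `transformation_id`, `direction` (`forward`|`reverse`) and
#' `work_kJ_per_mol`.
#'
#' @param ws A `work_set` or a list of them.
#' @param path Output file path.
#' @param header_comment Optional character vector of comment lines (written
#'   prefixed with `#` before the header).
#' @return `path`, invisibly.
#' @export
write_work_tsv <- function(ws, path, header_comment = NULL) {
  if (inherits(ws, "work_set")) ws <- list(ws)
  stopifnot(all(vapply(ws, inherits, logical(1), "work_set")))
  tab <- do.call(rbind, lapply(ws, function(w) {
    data.frame(
      transformation_id = w$transformation_id,
      direction = rep(c("forward", "reverse"),
                      c(length(w$forward), length(w$reverse))),
      work_kJ_per_mol = c(w$forward, w$reverse),
      stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a work table into a list of work sets
#'
#' Parses the tab-separated dialect written by [write_work_tsv()]; rows are
#' grouped by `transformation_id`.  Malformed rows (unknown direction,
#' non-numeric work) are reported with their line numbers.
#'
#' @param path Path to the work TSV.
#' @param temperature Temperature in kelvin attached to every work set.
#' @return Named list of `work_set` objects (names = transformation ids, in
#'   order of first appearance).
#' @export
read_work_tsv <- function(path, temperature = 310) {
  if (!file.exists(path)) stop("no such work table: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  body <- lines[!is_comment]
  if (length(body) < 2L)
    stop("work table '", path, "' contains no data rows", call. = FALSE)
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("transformation_id", "direction", "work_kJ_per_mol")
  if (!all(need %in% names(tab)))
    stop("work table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  # map data rows back to file line numbers (header is first non-comment line)
  line_no <- which(!is_comment)[-1L]
  work <- suppressWarnings(as.numeric(tab$work_kJ_per_mol))
  bad <- !tab$direction %in% c("forward", "reverse") | !is.finite(work)
  if (any(bad))
    stop("malformed work rows at line(s): ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  ids <- unique(tab$transformation_id)
  # duplicate (non-contiguous) id blocks are pooled; note it for the log
  runs <- rle(tab$transformation_id)$values
  if (anyDuplicated(runs))
    message("pooling non-contiguous rows for transformation_id(s): ",
            paste(unique(runs[duplicated(runs)]), collapse = ", "))
  out <- lapply(ids, function(id) {
    sel <- tab$transformation_id == id
    fw <- work[sel & tab$direction == "forward"]
    rv <- work[sel & tab$direction == "reverse"]
    if (length(fw) == 0L || length(rv) == 0L)
      stop("transformation '", id, "' is missing ",
           if (length(fw) == 0L) "forward" else "reverse", " rows",
           call. = FALSE)
    work_set(fw, rv, temperature = temperature, transformation_id = id)
  })
  stats::setNames(out, ids)
}
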