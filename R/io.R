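# Measurement CSV schema: scanner, tube_voltage_kv, method, thickness_mm,
# replicate, exposure. Decimal point, UTF-8, header required.
.measurement_cols <- c("scanner", "tube_voltage_kv", "method",
                       "thickness_mm", "replicate", "exposure")

#' Read measurement series from CSV
#'
#' Reads the standard measurement table (columns \code{scanner},
#' \code{tube_voltage_kv}, \code{method}, \code{thickness_mm},
#' \code{replicate}, \code{exposure}) and returns one
#' \code{\link{attenuation_series}} per (scanner, tube voltage, method)
#' group. Validation problems are reported with row numbers.
#'
#' @param path CSV file path.
#' @param strict Passed to \code{\link{attenuation_series}}.
#' @return Named list of \code{attenuation_series}.
#' @export
read_measurements <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  miss <- setdiff(.measurement_cols, names(df))
  if (length(miss))
    stop("measurement file lacks column(s): ", paste(miss, collapse = ", "))
  problems <- character()
  rows <- seq_len(nrow(df)) + 1L  # data rows, counting the header as line 1
  bad_exp <- !is.finite(df$exposure) | df$exposure <= 0
  if (any(bad_exp))
    problems <- c(problems, paste0(
      "row ", rows[bad_exp], ": exposure must be positive (got ",
      df$exposure[bad_exp], ")"))
  key <- paste(df$scanner, df$tube_voltage_kv, df$method,
               df$thickness_mm, df$replicate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    problems <- c(problems, paste0(
      "row ", rows[dup], ": duplicate (thickness, replicate) key"))
  if (length(problems))
    stop("invalid measurement file:\n  ",
         paste(problems, collapse = "\n  "))
  groups <- split(df, list(df$scanner, df$tube_voltage_kv, df$method),
                  drop = TRUE, sep = " | ")
  lapply(groups, function(gd) {
    gd <- gd[order(gd$thickness_mm, gd$replicate), ]
    attenuation_series(
      thickness_mm = unique(gd$thickness_mm),
      exposures = split(gd$exposure, factor(gd$thickness_mm)),
      method = gd$method[1L],
      scanner = gd$scanner[1L],
      tube_voltage_kv = gd$tube_voltage_kv[1L],
      strict = strict)
  })
}

#' Write measurement series to CSV
#'
#' Inverse of \code{\link{read_measurements}}: the write/read round trip is
#' lossless.
#'
#' @param series An \code{\link{attenuation_series}} or a list of them.
#' @param path Output CSV path.
#' @export
write_measurements <- function(series, path) {
  if (inherits(series, "attenuation_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    do.call(rbind, lapply(seq_along(s$thickness_mm), function(i)
      data.frame(scanner = s$scanner,
                 tube_voltage_kv = s$tube_voltage_kv,
                 method = s$method,
                 thickness_mm = s$thickness_mm[i],
                 replicate = seq_along(s$exposures[[i]]),
                 exposure = s$exposures[[i]])))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Build a structured analysis report
#'
#' Renders per-series HVL results at the standard reporting precision (HVL
#' to 2 decimals mmCu, effective energy to 1 decimal keV) and, when two or
#' more methods share scanner/voltage settings, a pairwise TOST equivalence
#' block.
#'
#' @param results List of \code{\link{analyze_series}} results.
#' @param margin TOST margin, mmCu (default 0.03).
#' @param alpha TOST significance level (default 0.05).
#' @return A list of class \code{hvl_report}: \code{results} (data.frame, one
#'   row per series) and \code{comparisons} (data.frame of pairwise TOST and
#'   difference summaries; NULL when no pairing is possible).
#' @export
run_report <- function(results, margin = 0.03, alpha = 0.05) {
  if (inherits(results, "hvl_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1L), "hvl_result")))
  tab <- do.call(rbind, lapply(results, format_hvl_result))
  full_hvl <- vapply(results, function(r) r$hvl_mm, numeric(1L))

  comparisons <- NULL
  methods <- unique(tab$method)
  if (length(methods) >= 2L) {
    cmp_rows <- list()
    for (i in seq_along(methods)) for (j in seq_along(methods)) {
      if (j <= i) next
      a_idx <- which(tab$method == methods[i])
      b_idx <- which(tab$method == methods[j])
      key_a <- paste(tab$scanner[a_idx], tab$tube_voltage_kv[a_idx])
      key_b <- paste(tab$scanner[b_idx], tab$tube_voltage_kv[b_idx])
      common <- intersect(key_a, key_b)
      if (length(common) < 3L) next
      a <- full_hvl[a_idx[match(common, key_a)]]
      b <- full_hvl[b_idx[match(common, key_b)]]
      ts <- tost_paired(a, b, margin = margin, alpha = alpha)
      ds <- difference_summary(a, b)
      cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
        method_a = methods[i], method_b = methods[j], n = ts$n,
        mean_diff_mmcu = ds$mean_signed, sd_diff_mmcu = ds$sd,
        mean_abs_diff_mmcu = ds$mean_abs,
        p_tost = ts$p, equivalent = ts$equivalent, margin_mmcu = margin)
    }
    if (length(cmp_rows)) comparisons <- do.call(rbind, cmp_rows)
  }
  structure(list(results = tab, comparisons = comparisons,
                 margin_mmcu = margin, alpha = alpha),
            class = "hvl_report")
}

#' @export
print.hvl_report <- function(x, ...) {
  cat("HVL analysis report\n===================\n")
  print(x$results, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat(sprintf("\nPairwise equivalence (TOST, margin +/-%g mmCu, alpha %g)\n",
                x$margin_mmcu, x$alpha))
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Write a report as JSON
#'
#' @param report An \code{\link{run_report}} object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "hvl_report"))
  jsonlite::write_json(
    list(results = report$results,
         comparisons = report$comparisons,
         margin_mmcu = report$margin_mmcu,
         alpha = report$alpha),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Validate a report JSON against the shipped schema
#'
#' Structural validation (required keys and primitive types) against
#' \code{inst/schema/report-schema.json}.
#'
#' @param path Path to a report JSON file.
#' @return TRUE (invisibly) if valid; otherwise an error listing problems.
#' @export
validate_report_json <- function(path) {
  schema <- jsonlite::read_json(
    system.file("schema", "report-schema.json", package = "copperhvl",
                mustWork = TRUE))
  doc <- jsonlite::read_json(path)
  problems <- character()
  for (key in names(schema$properties)) {
    required <- key %in% unlist(schema$required)
    if (is.null(doc[[key]])) {
      if (required) problems <- c(problems, paste0("missing key: ", key))
      next
    }
  }
  check_row <- function(row, props, where) {
    for (p in names(props)) {
      v <- row[[p]]
      if (is.null(v)) {
        problems <<- c(problems, paste0(where, ": missing field ", p))
      } else if (props[[p]]$type == "number" && !is.numeric(v)) {
        problems <<- c(problems, paste0(where, ": field ", p,
                                        " must be a number"))
      } else if (props[[p]]$type == "string" && !is.character(v)) {
        problems <<- c(problems, paste0(where, ": field ", p,
                                        " must be a string"))
      }
    }
  }
  res_props <- schema$properties$results$items$properties
  for (i in seq_along(doc$results))
    check_row(doc$results[[i]], res_props, paste0("results[", i, "]"))
  if (!is.null(doc$comparisons)) {
    cmp_props <- schema$properties$comparisons$items$properties
    for (i in seq_along(doc$comparisons))
      check_row(doc$comparisons[[i]], cmp_props,
                paste0("comparisons[", i, "]"))
  }
  if (length(problems))
    stop("report JSON fails schema validation:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(TRUE)
}
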