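#' Per-flexion-angle value series
#'
#' One scalar (e.g. von Mises stress, reaction force, contact stress) per
#' knee flexion angle.
#'
#' @param values numeric vector of finite values, one per angle.
#' @param angles strictly increasing flexion angles in degrees
#'   (default 0, 45, 90, 135).
#' @param quantity optional quantity label.
#' @return An `angle_series` tibble with columns `angle_deg`, `value`.
#' @export
angle_series <- function(values, angles = c(0, 45, 90, 135), quantity = NULL) {
  values <- as.numeric(values); angles <- as.numeric(angles)
  if (length(values) != length(angles))
    stop("`values` and `angles` must have equal length", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (is.unsorted(angles, strictly = TRUE))
    stop("angles must be strictly increasing", call. = FALSE)
  out <- tibble::tibble(angle_deg = angles, value = values)
  attr(out, "quantity") <- quantity
  class(out) <- c("angle_series", class(out))
  out
}

as_angle_series <- function(x) {
  if (inherits(x, "angle_series")) return(x)
  if (is.numeric(x)) return(angle_series(x))
  if (is.data.frame(x) && all(c("angle_deg", "value") %in% names(x)))
    return(angle_series(x$value, x$angle_deg))
  stop("cannot interpret input as an angle series", call. = FALSE)
}

#' Per-angle error rate between two angle series
#'
#' The discrepancy between a test method's and the reference method's
#' per-angle values. The default (`variant = "abs_sum"`) is the sum of
#' absolute per-angle differences, `eta = sum_i |TM_i - RM_i|` — the reading
#' of the published error-rate formula that reproduces every tabulated value;
#' the two literal root-mean-square readings are available for sensitivity
#' analysis.
#'
#' @param reference reference-method [angle_series()] (or numeric vector over
#'   the default angles).
#' @param test test-method series on the same angles.
#' @param variant `"abs_sum"` (default), `"mean_abs"` (`mean |diff|`), or
#'   `"rms"` (`sqrt(mean diff^2)`).
#' @return scalar error rate (same units as the series).
#' @examples
#' error_rate(c(7.447, 6.356, 5.67, 6.371), c(8.06, 6.694, 5.858, 6.082))
#' @export
error_rate <- function(reference, test,
                       variant = c("abs_sum", "mean_abs", "rms")) {
  variant <- match.arg(variant)
  reference <- as_angle_series(reference)
  test <- as_angle_series(test)
  if (nrow(reference) != nrow(test) ||
      any(reference$angle_deg != test$angle_deg))
    stop("reference and test series must share the same angle list",
         call. = FALSE)
  d <- test$value - reference$value
  switch(variant,
         abs_sum = sum(abs(d)),
         mean_abs = mean(abs(d)),
         rms = sqrt(mean(d^2)))
}

#' Read a per-angle FE summary table
#'
#' CSV schema: `method,quantity,angle_deg,value`; every (method, quantity)
#' pair must carry the same complete set of angles.
#'
#' @param path CSV path.
#' @return tibble of class `angle_table` with one row per
#'   method/quantity/angle.
#' @export
read_angle_table <- function(path) {
  tb <- tryCatch(readr::read_csv(path, show_col_types = FALSE,
                                 progress = FALSE),
                 error = function(e) stop("angle-table parse error: ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("method", "quantity", "angle_deg", "value")
  if (nrow(tb) == 0L || !all(need %in% names(tb)))
    stop("angle-table CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(tb$value) | is.na(tb$angle_deg))
  if (length(bad))
    stop("angle-table parse error: missing or non-numeric value at data row ",
         bad[1], call. = FALSE)
  angles <- sort(unique(tb$angle_deg))
  counts <- tb |> dplyr::count(.data$method, .data$quantity)
  if (any(counts$n != length(angles)))
    stop("every (method, quantity) pair must have values for all angles",
         call. = FALSE)
  class(tb) <- c("angle_table", class(tb))
  tb
}

#' @rdname read_angle_table
#' @param table an `angle_table` tibble.
#' @export
write_angle_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table)[c("method", "quantity",
                                              "angle_deg", "value")], path)
  invisible(path)
}

#' Extract one [angle_series()] from an angle table
#' @param table an `angle_table` tibble.
#' @param method,quantity row selectors.
#' @export
angle_table_series <- function(table, method, quantity) {
  sub <- table |>
    dplyr::filter(.data$method == !!method, .data$quantity == !!quantity) |>
    dplyr::arrange(.data$angle_deg)
  if (nrow(sub) == 0L)
    stop("no rows for method '", method, "', quantity '", quantity, "'",
         call. = FALSE)
  angle_series(sub$value, sub$angle_deg, quantity = quantity)
}

#' Cross-method error-rate report and ranking
#'
#' Computes the per-angle error rate of every non-reference method against
#' the reference for every quantity, picks the per-quantity winner (minimum
#' error rate), optionally adds a morphological experiment whose winner is
#' the method with the smallest absolute mean surface deviation, and ranks
#' methods by win count (ties broken by summed rank, then method id).
#'
#' @param table an `angle_table` tibble (see [read_angle_table()]).
#' @param reference name of the reference method (must appear in the table).
#' @param morphological optional named numeric vector of mean signed surface
#'   deviations (mm) per non-reference method, entering the tally as the
#'   `morphology` experiment.
#' @param variant error-rate variant, see [error_rate()].
#' @return An `error_rate_report`: list with tibbles `eta` (method, quantity,
#'   eta), `winners` (quantity, method, value), and `ranking` (method, wins,
#'   rank_sum).
#' @export
build_report <- function(table, reference, morphological = NULL,
                         variant = "abs_sum") {
  stopifnot(is.data.frame(table))
  methods <- setdiff(unique(table$method), reference)
  quantities <- unique(table$quantity)
  if (!reference %in% table$method)
    stop("reference method '", reference, "' not present in table",
         call. = FALSE)
  if (length(methods) < 1L || length(quantities) < 1L)
    stop("need at least one test method and one quantity", call. = FALSE)
  eta <- tidyr::expand_grid(method = methods, quantity = quantities) |>
    dplyr::mutate(eta = purrr::map2_dbl(.data$method, .data$quantity,
      function(m, q) error_rate(angle_table_series(table, reference, q),
                                angle_table_series(table, m, q),
                                variant = variant)))
  score <- eta |> dplyr::rename(value = "eta")
  if (!is.null(morphological)) {
    if (is.null(names(morphological)) ||
        !all(names(morphological) %in% methods))
      stop("`morphological` must be named by the non-reference methods",
           call. = FALSE)
    score <- dplyr::bind_rows(score,
      tibble::tibble(method = names(morphological), quantity = "morphology",
                     value = abs(as.numeric(morphological))))
  }
  winners <- score |>
    dplyr::group_by(.data$quantity) |>
    dplyr::filter(.data$value == min(.data$value)) |>
    dplyr::ungroup()
  ranking <- score |>
    dplyr::group_by(.data$quantity) |>
    dplyr::mutate(rank = rank(.data$value, ties.method = "min"),
                  is_win = .data$value == min(.data$value)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(wins = sum(.data$is_win), rank_sum = sum(.data$rank),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$wins), .data$rank_sum, .data$method)
  structure(list(eta = eta, winners = winners, ranking = ranking,
                 reference = reference, variant = variant),
            class = "error_rate_report")
}

#' @export
print.error_rate_report <- function(x, ...) {
  cat(sprintf("<error_rate_report> reference: %s\n", x$reference))
  wide <- x$eta |>
    tidyr::pivot_wider(names_from = "method", values_from = "eta")
  cat("\nError rates (eta):\n")
  print(as.data.frame(wide), row.names = FALSE, digits = 4)
  cat("\nRanking (by wins, then summed rank):\n")
  print(as.data.frame(x$ranking), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.error_rate_report <- function(x, ...) x$eta

#' @export
glance.error_rate_report <- function(x, ...) {
  tibble::tibble(reference = x$reference,
                 n_methods = nrow(x$ranking),
                 n_experiments = length(unique(c(x$eta$quantity,
                                                 x$winners$quantity))),
                 best_method = x$ranking$method[1],
                 best_wins = x$ranking$wins[1])
}

#' Write an error-rate report to JSON
#' @param report an `error_rate_report`.
#' @param path JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(reference = report$reference,
                            eta = report$eta, winners = report$winners,
                            ranking = report$ranking),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
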