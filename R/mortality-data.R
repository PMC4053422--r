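#' Build a mortality surface from cell records
#'
#' A mortality surface is the universal input of the package: one row per
#' age-group x calendar-year cell for a single sex, holding the death count
#' and the mid-year population (person-years of exposure). The constructor
#' validates completeness of the grid and the count invariants.
#'
#' @param data A data frame with columns `sex`, `age_group`, `year`, `deaths`,
#'   `population`; exactly one row per (age_group, year) cell.
#' @param ages Optional [age_scheme()]; inferred from the `age_group` labels
#'   when omitted.
#' @return A tibble of class `mortality_surface`, ordered by age then year,
#'   with the age scheme attached as attribute `ages`.
#' @details Invariants enforced: a single sex; consecutive years; a complete
#'   grid with no duplicate cells; integer `deaths >= 0`; `population > 0`;
#'   `deaths <= population`.
#' @seealso [read_surface()], [central_rates()], [simulate_surface()]
#' @export
mortality_surface <- function(data, ages = NULL) {
  req <- c("sex", "age_group", "year", "deaths", "population")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)[req]
  if (length(unique(data$sex)) != 1L) {
    stop("a mortality surface holds a single sex; got: ",
         paste(unique(data$sex), collapse = ", "), call. = FALSE)
  }
  if (is.null(ages)) ages <- infer_scheme(unique(as.character(data$age_group)))
  unknown <- setdiff(unique(as.character(data$age_group)), ages$labels)
  if (length(unknown)) {
    stop("unknown age label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  years <- sort(unique(data$year))
  if (length(years) < 1L || any(diff(years) != 1L)) {
    stop("missing cell: years must be consecutive; observed gaps at ",
         paste(years[which(diff(years) != 1L)], collapse = ", "), call. = FALSE)
  }
  key <- paste(data$age_group, data$year)
  if (anyDuplicated(key)) {
    stop("duplicate cell: ", key[duplicated(key)][1], call. = FALSE)
  }
  full <- expand.grid(age_group = ages$labels, year = years,
                      stringsAsFactors = FALSE)
  missing_cells <- setdiff(paste(full$age_group, full$year), key)
  if (length(missing_cells)) {
    stop("missing cell: ", missing_cells[1], call. = FALSE)
  }
  bad <- which(data$deaths < 0 | data$deaths != round(data$deaths))
  if (length(bad)) {
    stop("negative or non-integer deaths in row for cell ", key[bad[1]],
         call. = FALSE)
  }
  bad <- which(data$population <= 0)
  if (length(bad)) {
    stop("nonpositive exposure in row for cell ", key[bad[1]], call. = FALSE)
  }
  bad <- which(data$deaths > data$population)
  if (length(bad)) {
    stop("deaths exceed population in cell ", key[bad[1]], call. = FALSE)
  }
  data$age_group <- factor(data$age_group, levels = ages$labels)
  out <- dplyr::arrange(data, .data$age_group, .data$year)
  out$age_group <- as.character(out$age_group)
  out$deaths <- as.double(out$deaths)
  out <- tibble::tibble(sex = out$sex, age_group = out$age_group,
                        year = out$year, deaths = out$deaths,
                        population = out$population)
  structure(out, ages = ages,
            class = c("mortality_surface", class(tibble::tibble())))
}

#' Read a mortality surface from a delimited text file
#'
#' @param path Path to a CSV file with columns `sex`, `age_group`, `year`,
#'   `deaths`, `population`, one row per cell. Rows for other sexes are
#'   ignored.
#' @param sex Sex label to extract (e.g. `"male"`).
#' @return A [mortality_surface()].
#' @export
read_surface <- function(path, sex) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- dplyr::filter(df, .data$sex == !!sex)
  if (nrow(df) == 0L) {
    stop("no rows for sex '", sex, "' in ", path, call. = FALSE)
  }
  mortality_surface(df)
}

#' Central death rates and death probabilities
#'
#' Computes the central death rate `m = deaths / population` per cell and the
#' death probability under the constant-hazard-within-interval convention,
#' `q = 1 - exp(-m)`. The probability scale is what the Bayesian
#' age-period-cohort likelihood models; the rate scale is what Lee-Carter
#' models. Both live on the same surface so the two models are comparable.
#'
#' @param s A [mortality_surface()].
#' @return A tibble of class `rate_surface`: the surface columns plus `m` and
#'   `q`.
#' @examples
#' cfg <- sim_config(I = 3, J = 5, seed = 1)
#' s <- simulate_surface(cfg)$surface
#' central_rates(s)
#' @export
central_rates <- function(s) {
  stopifnot(inherits(s, "mortality_surface"))
  out <- dplyr::mutate(tibble::as_tibble(s),
                       m = .data$deaths / .data$population,
                       q = -expm1(-.data$m))
  structure(out, ages = attr(s, "ages"),
            class = c("rate_surface", class(tibble::tibble())))
}

#' Build a rate surface directly from central rates
#'
#' Mostly useful for constructed examples and for rate series without count
#' data; [central_rates()] is the usual route. `deaths` and `population` are
#' synthesised as `m * population` when absent (they only matter for the
#' Lee-Carter second-stage adjustment, which they then reproduce exactly).
#'
#' @param data Data frame with `sex`, `age_group`, `year`, `m` and optionally
#'   `deaths`, `population`.
#' @param population Default exposure used when the column is absent.
#' @param ages Optional [age_scheme()].
#' @return A `rate_surface` tibble (with `q = 1 - exp(-m)`).
#' @export
rate_surface <- function(data, population = 1e6, ages = NULL) {
  req <- c("sex", "age_group", "year", "m")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (any(data$m < 0)) stop("central rates must be nonnegative", call. = FALSE)
  if (is.null(data[["population"]])) data$population <- population
  if (is.null(data[["deaths"]])) data$deaths <- data$m * data$population
  if (is.null(ages)) ages <- infer_scheme(unique(as.character(data$age_group)))
  data$q <- -expm1(-data$m)
  data$age_group <- as.character(data$age_group)
  out <- dplyr::arrange(data[c("sex", "age_group", "year", "deaths",
                               "population", "m", "q")],
                        match(.data$age_group, ages$labels), .data$year)
  structure(out, ages = ages,
            class = c("rate_surface", class(tibble::tibble())))
}

#' Build a population projection from cell records
#'
#' @param data A data frame with columns `sex`, `age_group`, `year`,
#'   `population` (projected persons), one row per future cell.
#' @param ages Optional [age_scheme()]; inferred when omitted.
#' @return A tibble of class `population_projection`.
#' @export
population_projection <- function(data, ages = NULL) {
  req <- c("sex", "age_group", "year", "population")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)[req]
  if (is.null(ages)) ages <- infer_scheme(unique(as.character(data$age_group)))
  if (any(data$population <= 0)) stop("projected population must be positive",
                                      call. = FALSE)
  years <- sort(unique(data$year))
  if (any(diff(years) != 1L)) stop("projection years must be consecutive",
                                   call. = FALSE)
  data$age_group <- factor(data$age_group, levels = ages$labels)
  out <- dplyr::arrange(data, .data$age_group, .data$year)
  out$age_group <- as.character(out$age_group)
  out <- tibble::tibble(sex = out$sex, age_group = out$age_group,
                        year = out$year, population = out$population)
  structure(out, ages = ages,
            class = c("population_projection", class(tibble::tibble())))
}

#' Read a population projection from CSV
#' @inheritParams read_surface
#' @return A [population_projection()].
#' @export
read_projection <- function(path, sex) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- dplyr::filter(df, .data$sex == !!sex)
  if (nrow(df) == 0L) stop("no rows for sex '", sex, "' in ", path, call. = FALSE)
  population_projection(df)
}

#' Write a surface, forecast or scenario table as CSV
#'
#' Long-format, comma-delimited, header row. Forecast and scenario objects
#' are written with `estimate`, `lower`, `upper` and `quantity` columns and
#' round-trip through [read_forecast()].
#'
#' @param x A `mortality_surface`, `population_projection`, `rate_forecast`
#'   or `scenario_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forecast <- function(x, path) {
  df <- if (inherits(x, "rate_forecast")) {
    tibble::tibble(sex = x$sex, age_group = x$age_group, year = x$year,
                   estimate = x$q, lower = x$lower, upper = x$upper,
                   quantity = "death_probability")
  } else if (inherits(x, "scenario_result")) {
    cells <- x$cells
    tibble::tibble(sex = cells$sex, age_group = cells$age_group,
                   year = cells$year, estimate = cells$deaths,
                   lower = cells$lower, upper = cells$upper,
                   quantity = paste0("deaths_", x$scenario))
  } else if (inherits(x, "mortality_surface") ||
             inherits(x, "population_projection")) {
    tibble::as_tibble(x)
  } else {
    stop("don't know how to write an object of class ", class(x)[1],
         call. = FALSE)
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read back a forecast table written by [write_forecast()]
#' @param path CSV path.
#' @return A tibble with `sex`, `age_group`, `year`, `estimate`, `lower`,
#'   `upper`, `quantity`.
#' @export
read_forecast <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

surface_matrix <- function(s, what = "deaths") {
  ages <- attr(s, "ages")
  years <- sort(unique(s$year))
  m <- matrix(NA_real_, n_ages(ages), length(years),
              dimnames = list(ages$labels, years))
  m[cbind(match(s$age_group, ages$labels), match(s$year, years))] <- s[[what]]
  m
}
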