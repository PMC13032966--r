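#' Synthetic female background-mortality life table (Gompertz law)
#'
#' Builds an annual life table from the Gompertz mortality law
#' \deqn{q(age) = 1 - \exp(-a e^{b (age - 60)})}
#' a two-parameter, monotone hazard that tracks adult all-cause mortality
#' well. The defaults (`a = 0.0065`, `b = 0.085`) approximate published US
#' female life-table values over ages 60--100; the table is a synthetic
#' stand-in, not an official life table, and is documented as such.
#'
#' @param a Baseline annual cumulative hazard at age 60 (> 0).
#' @param b Log-slope of the hazard per year of age (> 0).
#' @param ages Integer ages covered (default 60--100).
#' @return A `life_table`: data.frame with columns `age`, `q_annual`.
#' @examples
#' lt <- gompertz_lifetable()
#' lt$q_annual[lt$age == 60]  # 1 - exp(-0.0065)
#' @export
gompertz_lifetable <- function(a = 0.0065, b = 0.085, ages = 60:100) {
  if (!(a > 0)) stop("Gompertz parameter a must be > 0", call. = FALSE)
  if (!(b > 0)) stop("Gompertz parameter b must be > 0", call. = FALSE)
  ages <- as.integer(ages)
  lt <- data.frame(age = ages,
                   q_annual = 1 - exp(-a * exp(b * (ages - 60))))
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Load the bundled synthetic life-table fixture
#'
#' @return A `life_table` data.frame.
#' @export
default_lifetable <- function() {
  path <- system.file("extdata", "lifetable_female_synthetic.csv",
                      package = "dpydcea")
  if (!nzchar(path)) return(gompertz_lifetable())
  read_lifetable(path)
}

#' Read/write a life table as two-column CSV
#'
#' @param path CSV path with columns `age`, `q_annual`.
#' @return `read_lifetable`: a `life_table`; `write_lifetable`: the path,
#'   invisibly.
#' @export
read_lifetable <- function(path) {
  lt <- utils::read.csv(path)
  stopifnot(all(c("age", "q_annual") %in% names(lt)))
  lt$age <- as.integer(lt$age)
  if (any(lt$q_annual <= 0 | lt$q_annual >= 1))
    stop("life-table q_annual must lie in (0, 1)", call. = FALSE)
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' @rdname read_lifetable
#' @param lt A `life_table`.
#' @export
write_lifetable <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "q_annual")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Monthly background mortality at a given age
#'
#' Converts the annual death probability for the (floored) current age to a
#' constant-hazard monthly probability, `1 - (1 - q)^(1/12)`, so that twelve
#' monthly cycles compound back to the annual value. Ages beyond the last
#' table row are clamped to the terminal row.
#'
#' @param lt A `life_table`.
#' @param age Attained age in (possibly fractional) years.
#' @return Monthly probability of background death.
#' @export
monthly_background_mortality <- function(lt, age) {
  yr <- pmin(pmax(floor(age), min(lt$age)), max(lt$age))
  q <- lt$q_annual[match(yr, lt$age)]
  1 - (1 - q)^(1 / 12)
}
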