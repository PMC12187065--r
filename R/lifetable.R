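#' Synthesize a general-population life table
#'
#' Generates an age-indexed table of annual death probabilities from a
#' Gompertz-Makeham hazard, `h(age) = c + a * exp(b * age)`, so that
#' `qx(age) = 1 - exp(-h(age))`. The defaults produce monotone geriatric
#' mortality resembling a Canadian general-population life table (about
#' 2.0% annual mortality at 70, 4.9% at 80, 12% at 90) and close the table
#' with `qx = 1` at the final age.
#'
#' @param makeham_c Age-independent hazard component (1/year).
#' @param gompertz_a Gompertz scale (1/year).
#' @param gompertz_b Gompertz shape (1/year of age).
#' @param age_min,age_max Integer age range covered (years).
#' @return A `lifetable`: a data.frame with columns `age` and `qx`.
#' @examples
#' lt <- synthesize_lifetable()
#' lt$qx[lt$age == 80]
#' @export
synthesize_lifetable <- function(makeham_c = 2e-4, gompertz_a = 2.5e-5,
                                 gompertz_b = 0.095, age_min = 65,
                                 age_max = 110) {
  stopifnot(makeham_c > 0, gompertz_a > 0, gompertz_b > 0, age_min < age_max)
  ages <- seq.int(age_min, age_max)
  qx <- 1 - exp(-(makeham_c + gompertz_a * exp(gompertz_b * ages)))
  if (any(qx[-length(qx)] >= 1)) {
    warning("hazard implies qx = 1 before the final age; clipping")
    qx <- pmin(qx, 1)
  }
  qx[length(qx)] <- 1  # table closure
  new_lifetable(ages, qx)
}

new_lifetable <- function(ages, qx) {
  structure(data.frame(age = as.integer(ages), qx = qx),
            class = c("lifetable", "data.frame"))
}

#' Load a life table from a delimited text file
#'
#' Expects two columns, age (integer years) and qx (annual death
#' probability), whitespace or tab separated, optional header. Ages must
#' be contiguous and ascending; qx in \[0, 1\].
#'
#' @param path Path to the file.
#' @return A validated `lifetable`.
#' @export
load_lifetable <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("age", "qx"),
                          colClasses = c("character", "character"))
  # tolerate a header row
  if (is.na(suppressWarnings(as.numeric(df$age[1])))) df <- df[-1, , drop = FALSE]
  age <- suppressWarnings(as.numeric(df$age))
  qx <- suppressWarnings(as.numeric(df$qx))
  for (i in seq_along(age)) {
    if (is.na(age[i]) || is.na(qx[i])) {
      stop("life table row ", i, ": non-numeric entry", call. = FALSE)
    }
    if (qx[i] < 0 || qx[i] > 1) {
      stop("life table row ", i, ": qx = ", qx[i], " outside [0, 1]",
           call. = FALSE)
    }
  }
  if (any(diff(age) != 1)) {
    bad <- which(diff(age) != 1)[1]
    stop("life table row ", bad + 1,
         ": ages must be contiguous and ascending", call. = FALSE)
  }
  new_lifetable(age, qx)
}

#' Write a life table to a delimited text file
#'
#' @param lt A `lifetable`.
#' @param path Output path; tab-separated with a header.
#' @return The path, invisibly.
#' @export
write_lifetable <- function(lt, path) {
  utils::write.table(as.data.frame(lt), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Monthly death probability at a given age, scaled by a relative risk
#'
#' Converts the annual death probability at the (completed-years) age to a
#' monthly hazard, `h_m = -log(1 - qx)/12`, scales the hazard by the
#' relative risk, and returns `1 - exp(-rr * h_m)`. Scaling on the hazard
#' rather than the probability keeps the result a probability for any
#' `rr > 0` (the model uses relative risks up to 4.46 at extreme ages).
#'
#' @param lt A `lifetable`.
#' @param age_in_months Age in months; the completed-years age indexes the
#'   table.
#' @param rr Relative risk of death versus the general population (> 0).
#' @return Monthly death probability in \[0, 1\].
#' @examples
#' lt <- synthesize_lifetable()
#' monthly_mortality(lt, 80 * 12, rr = 1)
#' monthly_mortality(lt, 80 * 12, rr = 4.46)
#' @export
monthly_mortality <- function(lt, age_in_months, rr = 1) {
  if (!(rr > 0)) stop("rr must be > 0", call. = FALSE)
  age <- floor(age_in_months / 12)
  i <- match(age, lt$age)
  if (is.na(i)) {
    stop("age ", age, " outside the life table range [", min(lt$age), ", ",
         max(lt$age), "]", call. = FALSE)
  }
  qx <- lt$qx[i]
  if (qx >= 1) return(1)
  h_m <- -log(1 - qx) / 12
  min(1, 1 - exp(-rr * h_m))
}
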