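#' Parameter sets of the in silico abdominal aortas
#'
#' The 21 thick-wall parameter sets used as in silico experiments. Each row
#' describes one aorta: the unloaded (closed, load-free) inner radius `R`
#' \[mm\] and wall thickness `H` \[mm\], the opening angle `phi0` \[degrees\]
#' of the cut-open, stress-free sector, the neo-Hookean matrix parameter `c`
#' \[kPa\], the collagen fiber parameters `k1` \[kPa\] and `k2` \[-\], the
#' fiber pitch angle `beta` \[degrees, from the circumferential direction\],
#' the in vivo axial pre-stretch `lam` \[-\], and the tabulated mean reduced
#' axial force `fred` \[N\] over the pressure sweep (a reference value, used
#' as a consistency oracle, not as a model input).
#'
#' Sets are grouped as `hg` (sets 1--6, high residual-stress gradient), `lc`
#' (sets 7--14, extremely low matrix parameter c), and `cs` (sets 15--21,
#' constant transmural strain at mean arterial pressure; taken to represent
#' healthy aortas).
#'
#' @return A tibble with 21 rows and columns
#'   `set, label, group, R, H, phi0, c, k1, k2, beta, lam, fred`.
#' @export
#' @examples
#' silico_aortas() %>% dplyr::count(group)
silico_aortas <- function() {
  path <- system.file("extdata", "silico_aortas.csv", package = "aortamech",
                      mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(label = "character"))
  out <- as_tibble(out)
  validate_silico(out)
  out
}

#' Identified parameter sets of the constitutive membrane model
#'
#' One row per in silico aorta: the identified unloaded inner radius `Ri`
#' \[mm\], the identified HGO parameters `c` \[kPa\], `k1` \[kPa\], `k2`
#' \[-\], `beta` \[degrees\], the identified axial stretch `lam` \[-\], and
#' the estimated constant reduced axial force `fred` \[N\] used during the
#' identification. A final summary row (`group == "clinic"`) holds the mean
#' identified parameters of a 30-subject clinical cohort; it has no matching
#' thick-wall geometry and cannot be simulated, so it is excluded unless
#' `include_clinic = TRUE`.
#'
#' @param include_clinic Keep the clinical summary row?
#' @return A tibble with columns
#'   `set, label, group, Ri, c, k1, k2, beta, lam, fred`.
#' @export
membrane_parameters <- function(include_clinic = FALSE) {
  path <- system.file("extdata", "membrane_parameters.csv",
                      package = "aortamech", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(label = "character"))
  out <- as_tibble(out)
  if (!include_clinic) out <- dplyr::filter(out, .data$group != "clinic")
  validate_membrane(out)
  out
}

#' Published per-set comparison metrics
#'
#' The reference values of the signed maximum difference and the
#' offset-corrected coefficient of determination between membrane-model
#' predictions and the in silico stress state, as tabulated in the original
#' evaluation (circumferential and axial stress components, load-bearing
#' fractions, and the reaction stress). Used to validate the regenerated
#' comparison tables. The axial isotropic component has no tabulated
#' coefficient of determination because the in silico stress is constant in
#' pressure there.
#'
#' @return A tibble with columns
#'   `set, direction, component, delta_max, r_hat_sq`.
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.csv",
                      package = "aortamech", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_silico <- function(x) {
  req <- c("set", "group", "R", "H", "phi0", "c", "k1", "k2", "beta", "lam", "fred")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop("corrupted silico aorta table: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  with(x, stopifnot(
    all(R > 0), all(H > 0), all(c > 0), all(k1 > 0), all(k2 > 0),
    all(beta >= 0 & beta < 90), all(lam >= 1),
    all(phi0 >= 0 & phi0 < 360),
    all(group %in% c("hg", "lc", "cs"))
  ))
  invisible(x)
}

validate_membrane <- function(x) {
  req <- c("set", "group", "Ri", "c", "k1", "k2", "beta", "lam")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop("corrupted membrane parameter table: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  with(x, stopifnot(
    all(Ri > 0), all(c > 0), all(k1 > 0), all(k2 > 0),
    all(beta >= 0 & beta < 90), all(lam >= 1)
  ))
  invisible(x)
}

# one row of silico_aortas() as a plain named list
as_artery <- function(artery) {
  if (is.data.frame(artery)) {
    stopifnot(nrow(artery) == 1)
    artery <- as.list(artery)
  }
  stopifnot(is.list(artery),
            all(c("R", "H", "phi0", "c", "k1", "k2", "beta", "lam") %in% names(artery)))
  artery
}

# one row of membrane_parameters() as a plain named list
as_membrane_params <- function(params) {
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1)
    params <- as.list(params)
  }
  stopifnot(is.list(params),
            all(c("Ri", "c", "k1", "k2", "beta", "lam") %in% names(params)))
  params
}
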