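#' Serialize a fitted vital-rate model to JSON
#'
#' Writes the parts of a fitted model needed for prediction and projection
#' — per-class intercepts and ROS' slopes, covariate slopes, the
#' interaction shapes `k`, scaling constants, training years and the
#' environmental covariance — as a JSON record, one file per posterior
#' sample. `read_vrm_json()` restores a model usable with
#' [predict.vrm()] and [project_population()].
#'
#' @param object a fitted [fit_vital_rates()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vrm_json <- function(object, path) {
  stopifnot(inherits(object, "vrm"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON serialization")
  part <- function(p)
    list(k = p$k, a_cls = as.list(p$a_cls), b_ros_cls = as.list(p$b_ros_cls),
         b_n = p$b_n, b_year = p$b_year, b_wl = p$b_wl, classes = p$classes)
  rec <- list(survival = part(object$survival),
              fecundity = part(object$fecundity),
              n_scaling = as.list(object$n_scaling),
              year_center = object$year_center,
              years = object$years,
              sigma = unclass(object$sigma))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vrm_json
#' @export
read_vrm_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON serialization")
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  part <- function(p)
    list(k = p$k, a_cls = unlist(p$a_cls), b_ros_cls = unlist(p$b_ros_cls),
         b_n = p$b_n, b_year = p$b_year, b_wl = p$b_wl,
         classes = p$classes)
  sigma <- as.matrix(rec$sigma)
  nm <- c(paste0("S_", SURV_CLASSES), paste0("F_", FEC_CLASSES))
  dimnames(sigma) <- list(nm, nm)
  structure(list(survival = part(rec$survival),
                 fecundity = part(rec$fecundity),
                 n_scaling = unlist(rec$n_scaling),
                 year_center = rec$year_center,
                 years = rec$years,
                 sigma = sigma),
            class = "vrm")
}
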