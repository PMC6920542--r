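#' Read / write datasets as tab-separated text
#'
#' Three layouts are supported. `single_exposure`: columns `Y`, `X`,
#' `Z1..ZJ` and optionally `W` and `U`. `mediation`: columns `Y`, `X1`,
#' `X2`, then `I1.*` columns, then `I2.*` columns (the J1/J2 split is read
#' from the column prefixes, or forced with `J1`). `summary`: columns
#' `variant_id`, `beta_X`, `se_X`, `beta_Y`, `se_Y`. Doses are validated to
#' lie in \{0,1,2\} with the offending cell reported. The
#' write/read round trip reproduces the container exactly.
#'
#' @param path File path.
#' @param layout One of `"single_exposure"`, `"mediation"`, `"summary"`.
#' @param J1 Optional explicit size of the I1 instrument set (mediation).
#' @return An `mr_data`, `mr_mediation_data` or `instrument_summary`.
#' @export
read_dataset <- function(path, layout = c("single_exposure", "mediation",
                                          "summary"), J1 = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  check_doses <- function(M, cols) {
    for (j in seq_len(ncol(M))) {
      bad <- which(!M[, j] %in% c(0, 1, 2))
      if (length(bad))
        stop(sprintf("dose outside {0,1,2} at row %d, column '%s'",
                     bad[1], cols[j]))
    }
  }
  if (layout == "summary") {
    need <- c("variant_id", "beta_X", "se_X", "beta_Y", "se_Y")
    if (!all(need %in% names(d)))
      stop("summary layout requires columns: ", paste(need, collapse = ", "))
    d <- d[, need]
    class(d) <- c("instrument_summary", "data.frame")
    return(d)
  }
  if (layout == "single_exposure") {
    if (!all(c("Y", "X") %in% names(d)))
      stop("single_exposure layout requires columns Y and X")
    zc <- grep("^Z", names(d), value = TRUE)
    if (!length(zc)) stop("no instrument (Z*) columns found")
    Z <- as.matrix(d[, zc, drop = FALSE])
    check_doses(Z, zc)
    return(mr_data(Y = d$Y, X = d$X, Z = Z,
                   W = if ("W" %in% names(d)) d$W else NULL,
                   U = if ("U" %in% names(d)) d$U else NULL))
  }
  if (!all(c("Y", "X1", "X2") %in% names(d)))
    stop("mediation layout requires columns Y, X1 and X2")
  if (is.null(J1)) {
    c1 <- grep("^I1\\.", names(d), value = TRUE)
    c2 <- grep("^I2\\.", names(d), value = TRUE)
  } else {
    ic <- setdiff(names(d), c("Y", "X1", "X2", "U"))
    c1 <- ic[seq_len(J1)]; c2 <- ic[-seq_len(J1)]
  }
  if (!length(c1) || !length(c2)) stop("could not locate I1/I2 dose columns")
  I1 <- as.matrix(d[, c1, drop = FALSE]); I2 <- as.matrix(d[, c2, drop = FALSE])
  check_doses(I1, c1); check_doses(I2, c2)
  mr_mediation_data(Y = d$Y, X1 = d$X1, X2 = d$X2, I1 = I1, I2 = I2,
                    U = if ("U" %in% names(d)) d$U else NULL)
}

#' @rdname read_dataset
#' @param data An `mr_data` or `mr_mediation_data`.
#' @export
write_dataset <- function(data, path) {
  if (inherits(data, "mr_data")) {
    df <- data.frame(Y = data$Y, X = data$X, data$Z, check.names = FALSE)
    if (!is.null(data$W)) df$W <- data$W
    if (!is.null(data$U)) df$U <- data$U
  } else if (inherits(data, "mr_mediation_data")) {
    df <- data.frame(Y = data$Y, X1 = data$X1, X2 = data$X2,
                     data$I1, data$I2, check.names = FALSE)
    if (!is.null(data$U)) df$U <- data$U
  } else stop("unsupported data container")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# schema of recognised config keys per subcommand
.config_schema <- list(
  simulate = c("scenario", "theta_regime", "seed", "out", "redraw_genotypes"),
  fit = c("data", "prior", "chains", "warmup", "iter", "seed", "out",
          "interaction", "level"),
  wme = c("data", "n_boot", "level", "seed", "out"),
  egger = c("data", "level", "out"),
  mediate = c("data", "J1", "prior", "chains", "warmup", "iter", "seed",
              "out", "level"),
  evaluate = c("scenario", "methods", "reps", "n_boot", "seed", "out",
               "chains", "warmup", "iter")
)

#' Read and validate a run configuration
#'
#' JSON key-value file; unknown keys are rejected and defaults are
#' materialized so that the effective configuration can be persisted next to
#' the outputs.
#'
#' @param path JSON file path.
#' @param subcommand One of the CLI subcommands.
#' @return Named list of settings.
#' @export
read_run_config <- function(path, subcommand) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- .config_schema[[subcommand]]
  if (is.null(known)) stop("unknown subcommand: ", subcommand)
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  cfg
}
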