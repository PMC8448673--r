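#' Write / read single-channel sweeps as tidy CSV
#'
#' Long format with columns `time_s`, `sweep_id`, `current_pA`.
#'
#' @param ss a [sweep_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweeps_csv <- function(ss, path) {
  stopifnot(inherits(ss, "sweep_set"))
  n <- length(ss$sweeps[[1]])
  df <- data.frame(
    time_s = rep((seq_len(n) - 1L) / ss$fs, length(ss$sweeps)),
    sweep_id = rep(seq_along(ss$sweeps), each = n),
    current_pA = unlist(ss$sweeps))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweeps_csv
#' @param fs,unitary_current,filter_hz metadata for the reconstructed set
#'   (the CSV stores only samples).
#' @export
read_sweeps_csv <- function(path, fs = 10000, unitary_current = 1.0,
                            filter_hz = 2000) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "sweep_id", "current_pA") %in% names(df)))
  sweeps <- lapply(split(df, df$sweep_id),
                   function(s) s$current_pA[order(s$time_s)])
  sweep_set(unname(sweeps), fs = fs, unitary_current = unitary_current,
            filter_hz = filter_hz)
}

#' Serialize a level sequence or gating parameters to JSON
#'
#' @param x a `level_sequence` or `coupled_markov_params`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_json_obj <- function(x, path) {
  if (inherits(x, "level_sequence")) {
    obj <- list(type = "level_sequence", levels = x$levels, dt = x$dt,
                n_channels = x$n_channels)
  } else if (inherits(x, "coupled_markov_params")) {
    obj <- list(type = "coupled_markov_params", n_channels = x$n_channels,
                kappa = x$kappa, rho = x$rho, sigma_c = x$sigma_c,
                unitary_current = x$unitary_current, dt = x$dt)
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_json_obj
#' @export
read_json_obj <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    level_sequence = level_sequence(obj$levels, obj$dt, obj$n_channels),
    coupled_markov_params = coupled_markov_params(
      obj$n_channels, obj$kappa, obj$rho, obj$sigma_c,
      obj$unitary_current, obj$dt),
    stop("unknown object type: ", obj$type))
}

#' Export a transition matrix as CSV
#'
#' @param tm a `transition_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(tm, path) {
  utils::write.csv(as.data.frame(unclass(tm)), path, row.names = TRUE)
  invisible(path)
}

#' Read a tidy pressure-myography CSV
#'
#' Expects columns `time_s`, `pressure_mmHg`, `diameter_um`, `condition`
#' with condition in `{active, passive, KCl}`. KCl rows become the pre/post
#' challenge diameters (pre = first half of the KCl block, post = final
#' 30 s).
#'
#' @param path CSV path.
#' @return A [diameter_dataset()].
#' @export
read_myography_csv <- function(path) {
  df <- utils::read.csv(path)
  kcl <- NULL
  kc <- df[df$condition == "KCl", ]
  if (nrow(kc) > 0) {
    tm <- stats::median(kc$time_s)
    kcl <- list(d_pre = mean(kc$diameter_um[kc$time_s < tm]),
                d_kcl = mean(kc$diameter_um[kc$time_s >= max(kc$time_s) - 30]))
  }
  diameter_dataset(df[df$condition %in% c("active", "passive"), ], kcl = kcl)
}
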