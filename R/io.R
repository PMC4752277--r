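#' @name file_formats
#' @title File formats used by the package
#' @description
#' All artifacts are plain text. Trajectories are CSV with header
#' `time_h,S,L,SL,Q,V`. Observations are long-format CSV
#' `mouse_id,time_h,compartment,count_per_g,censored` with `#`-prefixed
#' provenance comments (seed, detection limit, generating parameters).
#' Parameter configurations are flat `key = value` files with the eight
#' keys `d,r,k,x,l,y,a,g`. Assay series are CSV `time_h,value` (plus
#' `mouse_id` for ratio series) with the kind and, for adsorption assays,
#' the bacterial density `B` in the header block. Sweeps are CSV
#' `parameter,value,initial_ratio,final_ratio`. Scientific notation is
#' accepted on read and emitted with 9 significant digits.
NULL

fmt_num <- function(x) sprintf("%.9g", x)

write_header <- function(path, meta) {
  lines <- character()
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.null(v) || length(v) == 0) next
    lines <- c(lines, paste0("# ", nm, ": ",
                             paste(fmt_char(v), collapse = " ")))
  }
  writeLines(lines, path)
}

fmt_char <- function(v) if (is.numeric(v)) fmt_num(v) else as.character(v)

read_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

append_csv <- function(df, path, num_cols) {
  for (cc in num_cols) df[[cc]] <- fmt_num(df[[cc]])
  cat(paste(names(df), collapse = ","), "\n", sep = "", file = path,
      append = file.exists(path) && file.size(path) > 0)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE, append = TRUE)
}

#' Write / read a parameter configuration file
#'
#' Flat `key = value` text with the eight parameter keys.
#'
#' @param params A `phage_params` vector.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   a validated `phage_params`.
#' @export
write_params <- function(params, path) {
  p <- validate_params(params)
  writeLines(sprintf("%s = %s", PARAM_NAMES, fmt_num(unclass(p))), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  vals <- numeric()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^\\s*([a-z])\\s*[=:]?\\s*([-+0-9.eE]+)\\s*$", ln))[[1]]
    if (length(m) != 3) {
      stop("cannot parse parameter file line ", i, ": '", lines[i], "'",
           call. = FALSE)
    }
    vals[m[2]] <- as.numeric(m[3])
  }
  missing <- setdiff(PARAM_NAMES, names(vals))
  if (length(missing) > 0) {
    stop("parameter file lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_params(vals[PARAM_NAMES])
}

#' Write / read a trajectory CSV
#'
#' @param trajectory A `phage_trajectory`.
#' @param path File path.
#' @return `read_trajectory` returns a data.frame with columns
#'   `time_h,S,L,SL,Q,V`.
#' @export
write_trajectory <- function(trajectory, path) {
  p <- attr(trajectory, "params", exact = TRUE)
  meta <- list()
  if (!is.null(p)) meta$params <- paste(sprintf("%s=%s", PARAM_NAMES,
                                                fmt_num(unclass(p))),
                                        collapse = " ")
  sw <- attr(trajectory, "switch_time", exact = TRUE)
  if (!is.null(sw)) meta$switch_time <- sw
  write_header(path, meta)
  append_csv(as.data.frame(trajectory)[, c("time_h", STATE_NAMES)], path,
             c("time_h", STATE_NAMES))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_h", STATE_NAMES)
  if (!all(need %in% names(df))) {
    stop("trajectory file needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df[, need]
}

#' Write / read a long-format observation CSV
#'
#' @param obs A `fecal_observations` data.frame.
#' @param path File path.
#' @return `read_observations` returns a `fecal_observations` data.frame;
#'   provenance from the header (seed, detection limit, parameters) is
#'   restored as attributes.
#' @export
write_observations <- function(obs, path) {
  obs <- obs_check(obs)
  meta <- list()
  cfg <- attr(obs, "config", exact = TRUE)
  if (!is.null(cfg)) {
    meta$scenario <- cfg$scenario
    meta$seed <- cfg$seed
  }
  dl <- attr(obs, "detection_limit", exact = TRUE)
  if (!is.null(dl)) meta$detection_limit <- dl
  p <- attr(obs, "params", exact = TRUE)
  if (!is.null(p)) meta$params <- paste(sprintf("%s=%s", PARAM_NAMES,
                                                fmt_num(unclass(p))),
                                        collapse = " ")
  write_header(path, meta)
  append_csv(obs[, c("mouse_id", "time_h", "compartment", "count_per_g",
                     "censored")], path, c("time_h", "count_per_g"))
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  meta <- read_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  df <- obs_check(df)
  if (!is.null(meta$detection_limit)) {
    attr(df, "detection_limit") <- as.numeric(meta$detection_limit)
  }
  if (!is.null(meta$seed)) attr(df, "seed") <- as.integer(as.numeric(meta$seed))
  if (!is.null(meta$scenario)) attr(df, "scenario") <- meta$scenario
  if (!is.null(meta$params)) {
    kv <- strsplit(strsplit(meta$params, "\\s+")[[1]], "=")
    vals <- stats::setNames(vapply(kv, function(z) as.numeric(z[2]), numeric(1)),
                            vapply(kv, `[`, character(1), 1))
    attr(df, "params") <- validate_params(vals)
  }
  class(df) <- c("fecal_observations", "data.frame")
  df
}

#' Write / read an assay CSV
#'
#' @param assay An `assay_dataset`.
#' @param path File path.
#' @export
write_assay <- function(assay, path) {
  stopifnot(inherits(assay, "assay_dataset"))
  meta <- c(list(kind = assay$kind),
            if (!is.null(assay$B)) list(B = assay$B),
            assay$meta[vapply(assay$meta, function(z)
              is.numeric(z) || is.character(z), logical(1))])
  write_header(path, meta)
  num_cols <- intersect(names(assay$data), c("time_h", "value",
                                             "n_centres", "n_plated"))
  append_csv(assay$data, path, num_cols)
  invisible(path)
}

#' @rdname write_assay
#' @export
read_assay <- function(path) {
  meta <- read_header(path)
  if (is.null(meta$kind)) stop("assay file lacks a '# kind:' header",
                               call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  B <- if (!is.null(meta$B)) as.numeric(meta$B) else NULL
  assay_dataset(meta$kind, df, B = B,
                meta = meta[setdiff(names(meta), c("kind", "B"))])
}

#' Write / read a sweep CSV
#'
#' @param sweep A `phage_sweep` data.frame.
#' @param path File path.
#' @export
write_sweep <- function(sweep, path) {
  num_cols <- setdiff(names(sweep), c("parameter", "initial_ratio"))
  hz <- attr(sweep, "horizon", exact = TRUE)
  write_header(path, if (!is.null(hz)) list(horizon = hz) else list())
  append_csv(as.data.frame(sweep), path, num_cols)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  meta <- read_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!is.null(meta$horizon)) attr(df, "horizon") <- as.numeric(meta$horizon)
  class(df) <- c("phage_sweep", "data.frame")
  df
}

#' Write a fit report
#'
#' Key-value report of a `phage_fit` plus a machine-readable CSV table of
#' estimates and intervals.
#'
#' @param fit A `phage_fit`.
#' @param path Report path; the estimates table goes to
#'   `<path>.estimates.csv`.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "phage_fit"))
  lines <- c(paste0("data_ref: ", fit$data_ref),
             paste0("objective: ", fmt_num(fit$objective)))
  if (!is.null(fit$seed)) lines <- c(lines, paste0("seed: ", fit$seed))
  if (!is.null(fit$n_boot)) lines <- c(lines, paste0("n_boot: ", fit$n_boot))
  if (length(fit$flags)) {
    lines <- c(lines, paste0("flags: ", paste(fit$flags, collapse = ";")))
  }
  for (nm in names(fit$estimates)) {
    lines <- c(lines, sprintf("%s: %s", nm, fmt_num(fit$estimates[[nm]])))
  }
  writeLines(lines, path)
  est <- data.frame(parameter = names(fit$estimates),
                    estimate = as.numeric(fit$estimates),
                    lower = NA_real_, upper = NA_real_)
  if (!is.null(fit$ci95)) {
    i <- match(rownames(fit$ci95), est$parameter)
    est$lower[i] <- fit$ci95[, 1]
    est$upper[i] <- fit$ci95[, 2]
  }
  append_csv(est, paste0(path, ".estimates.csv"),
             c("estimate", "lower", "upper"))
  invisible(path)
}
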