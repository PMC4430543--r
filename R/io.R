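#' Write a trajectory to a plain-text file
#'
#' Serializes an `fhh_trajectory` as a CSV table (one column per recorded
#' series; space-time voltage matrices become `v_1..v_n` columns) preceded
#' by a single `#`-prefixed JSON metadata line carrying `alpha`, `dt`, the
#' memory policy, and node positions where applicable.  The round trip
#' through [read_trajectory] is lossless to stored precision (17 significant
#' digits).
#'
#' @param traj an `fhh_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fhh_trajectory"))
  series <- c("v", "m", "h", "n", "I_Na", "I_K", "I_L", "v_mem")
  cols <- list(time = traj$times)
  for (s in series) {
    val <- traj[[s]]
    if (is.null(val)) next
    if (is.matrix(val)) {
      for (j in seq_len(ncol(val))) cols[[paste0(s, "_", j)]] <- val[, j]
    } else cols[[s]] <- val
  }
  meta <- list(alpha = traj$alpha, dt = traj$dt, memory = traj$memory,
               n_samples = length(traj$times))
  if (!is.null(traj$x)) meta$x <- traj$x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
  df <- as.data.frame(lapply(cols, function(v) sprintf("%.17g", v)),
                      check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param required series that must be present on read; a missing one is a
#'   schema error.
#' @return `read_trajectory`: the reconstructed `fhh_trajectory`.
#' @export
read_trajectory <- function(path, required = c("v")) {
  lines <- readLines(path, n = 1L)
  if (!startsWith(lines, "# "))
    stop("not a trajectory file: missing JSON metadata header", call. = FALSE)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = "numeric")
  out <- list(times = df$time)
  plain <- setdiff(names(df), "time")
  bases <- unique(sub("_[0-9]+$", "", plain))
  for (b in bases) {
    cn <- grep(paste0("^", b, "(_[0-9]+)?$"), plain, value = TRUE)
    if (length(cn) == 1L && cn == b) out[[b]] <- df[[b]]
    else {
      ord <- cn[order(as.integer(sub(".*_", "", cn)))]
      out[[b]] <- as.matrix(df[ord])
      dimnames(out[[b]]) <- NULL
    }
  }
  missing <- setdiff(required, names(out))
  if (length(missing))
    stop("trajectory file is missing required series: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out$alpha <- meta$alpha; out$dt <- meta$dt; out$memory <- meta$memory
  if (!is.null(meta$x)) out$x <- meta$x
  cls <- "fhh_trajectory"
  if (!is.null(out$x)) cls <- c("fhh_cable_trajectory", cls)
  structure(out, class = cls)
}
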