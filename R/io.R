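#' Write a density field as delimited text
#'
#' Tab-separated columns \code{x}, \code{value}, preceded by a one-line
#' header comment carrying \code{dx}, \code{x0}, \code{boundary} and
#' \code{time}.
#'
#' @param field a \code{\link{density_field}}.
#' @param path output file path.
#' @export
write_density_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dx=%.17g x0=%.17g boundary=%s time=%.17g",
                     field$dx, field$x[1], field$boundary, field$time), con)
  utils::write.table(data.frame(x = field$x, value = field$values),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a density field written by \code{\link{write_density_field}}
#' @param path input file path.
#' @return a \code{\link{density_field}}.
#' @export
read_density_field <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z0-9]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(
    lapply(strsplit(kv, "="), `[[`, 2),
    vapply(strsplit(kv, "="), `[[`, "", 1))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  density_field(df$x, df$value, boundary = meta$boundary,
                time = as.numeric(meta$time))
}

#' Write a field trajectory as delimited text
#'
#' Long format: columns \code{time}, \code{x}, \code{value}, with the same
#' header line as \code{\link{write_density_field}}.
#'
#' @param traj a \code{field_trajectory}.
#' @param path output file path.
#' @export
write_field_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dx=%.17g x0=%.17g boundary=%s time=%.17g",
                     traj$dx, traj$x[1], traj$boundary, traj$times[1]), con)
  df <- do.call(rbind, lapply(seq_along(traj$times), function(i)
    data.frame(time = traj$times[i], x = traj$x, value = traj$values[[i]])))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field trajectory written by \code{\link{write_field_trajectory}}
#' @param path input file path.
#' @return a \code{field_trajectory}.
#' @export
read_field_trajectory <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z0-9]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(
    lapply(strsplit(kv, "="), `[[`, 2),
    vapply(strsplit(kv, "="), `[[`, "", 1))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  times <- unique(df$time)
  x <- df$x[df$time == times[1]]
  vals <- lapply(times, function(t) df$value[df$time == t])
  structure(list(times = times, values = vals, x = x, dx = x[2] - x[1],
                 boundary = meta$boundary, clipped_mass = NA_real_),
            class = "field_trajectory")
}

#' Write individual-based trajectory totals
#'
#' Tab-separated \code{time}, \code{n}, \code{mass}, \code{mean_density}.
#'
#' @param traj an \code{ibm_trajectory}.
#' @param path output file path.
#' @export
write_ibm_totals <- function(traj, path) {
  utils::write.table(
    data.frame(time = traj$times, n = traj$n, mass = traj$mass,
               mean_density = traj$mean_density),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write recorded atom positions
#'
#' Long-format \code{time}, \code{id}, \code{x} for trajectories run with
#' \code{store_snapshots = TRUE}.
#'
#' @param traj an \code{ibm_trajectory}.
#' @param path output file path.
#' @export
write_ibm_snapshots <- function(traj, path) {
  if (is.null(traj$snapshots)) stop("trajectory holds no snapshots")
  df <- do.call(rbind, lapply(seq_along(traj$times), function(i) {
    xs <- traj$snapshots[[i]]
    if (length(xs) == 0L) return(NULL)
    data.frame(time = traj$times[i], id = seq_along(xs), x = xs)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a lookdown event log
#' @param run a \code{\link{lookdown_run}}.
#' @param path output file path.
#' @export
write_event_log <- function(run, path) {
  utils::write.table(run$events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write lineage paths as delimited text
#'
#' Long-format \code{path}, \code{s}, \code{x}.
#'
#' @param ens a \code{lineage_ensemble}.
#' @param path output file path.
#' @export
write_lineage_paths <- function(ens, path) {
  df <- do.call(rbind, lapply(seq_len(nrow(ens$paths)), function(i)
    data.frame(path = i, s = ens$s, x = ens$paths[i, ])))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
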