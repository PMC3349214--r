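#' Plot an MI profile
#'
#' Line plot of mutual information against the sampled parameter; the
#' interpolation artifacts (stairs for nearest neighbour, inverted arches for
#' partial volume at matched resolutions) are directly visible.
#'
#' @param object An [mi_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_profile <- function(object, ...) {
  require_ggplot()
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mi)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = paste0(attr(object, "parameter"), " (",
                 if (attr(object, "parameter") %in% c("tx", "ty", "tz"))
                   "mm" else "degrees", ")"),
      y = "mutual information (bits)",
      title = sprintf("MI profile - %s, DF = %s",
                      toupper(attr(object, "scheme")), attr(object, "df"))
    )
}

#' Plot per-generation GA fitness
#'
#' @param x A `registration_result` from [ga_optimize()] or
#'   [register_volumes()].
#' @return A ggplot object.
#' @export
plot_ga_trace <- function(x) {
  require_ggplot()
  stopifnot(inherits(x, "registration_result"), !is.null(x$ga_trace))
  d <- x$ga_trace
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best), linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linetype = "dashed") +
    ggplot2::labs(x = "generation", y = "fitness (MI, bits)",
                  title = "GA best (solid) and mean (dashed) fitness")
}

#' Plot per-parameter error spreads of an optimizer comparison
#'
#' @param comparison A named list of `error_summary` objects as returned by
#'   [optimizer_comparison()].
#' @return A ggplot object (boxplots of signed errors per parameter and
#'   method).
#' @export
plot_optimizer_comparison <- function(comparison) {
  require_ggplot()
  long <- do.call(rbind, lapply(names(comparison), function(m) {
    runs <- comparison[[m]]$runs
    do.call(rbind, lapply(param_names, function(p) {
      data.frame(method = m, parameter = p,
                 error = runs[[paste0("error_", p)]])
    }))
  }))
  long$parameter <- factor(long$parameter, levels = param_names)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$error,
                                     fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "signed error (mm / degrees)",
                  title = "Registration error by optimizer")
}

#' Export an MI profile as CSV
#'
#' Writes `position, mi` rows preceded by comment lines recording the
#' scheme, downsampling factor, bin count and parameter, so the file is
#' self-describing.
#'
#' @param profile An [mi_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  hdr <- sprintf("# parameter=%s scheme=%s df=%s bins=%s step=%s",
                 attr(profile, "parameter"), attr(profile, "scheme"),
                 attr(profile, "df"), attr(profile, "bins"),
                 attr(profile, "step"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(profile)[, c("position", "mi")], con,
                   row.names = FALSE)
  invisible(path)
}

#' Read an MI profile CSV written by [write_profile_csv()]
#'
#' @param path File path.
#' @return A tibble with `position` and `mi`.
#' @export
read_profile_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
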