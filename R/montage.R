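#' Default 48-channel probe montage
#'
#' Builds the montage used throughout the package: 48 optical channels from a
#' 24-source / 16-detector layout with 3 cm source-detector separation,
#' grouped into six cortical regions of interest (prefrontal, motor and
#' occipital cortex, left and right).  Two channels (20 and 43) sit on a
#' region boundary and are members of two regions each; this overlap is kept
#' deliberately and region summaries count them in both regions.
#'
#' @param n_channels Number of channels.  Only montages whose region map fits
#'   inside `1..n_channels` are valid; the shipped region map is defined for
#'   the standard 48-channel layout.
#' @return An object of class `fnirs_montage`: a list with `n_channels`,
#'   `channels` (integer ids) and `regions` (named list of integer channel-id
#'   vectors for `R_PFC`, `L_PFC`, `R_MC`, `L_MC`, `R_OC`, `L_OC`).
#' @examples
#' m <- default_montage()
#' sapply(m$regions, length)
#' @export
default_montage <- function(n_channels = 48L) {
  regions <- list(
    R_PFC = c(3L, 4L, 5L, 6L, 7L, 17L, 18L, 19L, 20L, 21L),
    L_PFC = c(8L, 9L, 10L, 11L, 12L, 20L, 22L, 23L, 24L, 25L),
    R_MC  = c(1L, 2L, 15L, 16L, 28L, 35L, 36L, 37L, 38L, 40L),
    L_MC  = c(13L, 14L, 26L, 27L, 29L, 30L, 31L, 32L, 33L, 34L),
    R_OC  = c(39L, 41L, 43L, 45L, 46L),
    L_OC  = c(42L, 43L, 44L, 47L, 48L)
  )
  new_montage(n_channels = n_channels, regions = regions)
}

#' Construct a montage
#'
#' @param n_channels Total number of channels.
#' @param regions Named list mapping region names to integer channel-id
#'   vectors, each a subset of `1..n_channels`.
#' @return A `fnirs_montage` object.
#' @export
new_montage <- function(n_channels, regions) {
  n_channels <- as.integer(n_channels)
  stopifnot(length(n_channels) == 1L, n_channels >= 1L)
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("every region must be named")
  regions <- lapply(regions, function(ch) sort(unique(as.integer(ch))))
  for (rn in names(regions)) {
    ch <- regions[[rn]]
    if (length(ch) == 0L)
      stop("region '", rn, "' has no channels")
    if (any(ch < 1L | ch > n_channels))
      stop("region '", rn, "' references channels outside 1..", n_channels)
  }
  structure(list(n_channels = n_channels,
                 channels = seq_len(n_channels),
                 regions = regions),
            class = "fnirs_montage")
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat("fNIRS montage:", x$n_channels, "channels,",
      length(x$regions), "regions\n")
  for (rn in names(x$regions))
    cat(sprintf("  %-6s %s\n", rn, paste(x$regions[[rn]], collapse = " ")))
  invisible(x)
}

#' Write / read a montage as YAML
#'
#' @param montage A `fnirs_montage`.
#' @param path File path.
#' @return `read_montage` returns a `fnirs_montage`; `write_montage` returns
#'   `path` invisibly.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "fnirs_montage"))
  yaml::write_yaml(list(n_channels = montage$n_channels,
                        regions = montage$regions), path)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  spec <- yaml::read_yaml(path)
  new_montage(spec$n_channels, spec$regions)
}
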