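#' Declare anatomical axis directions of an image array
#'
#' Sagittal MRI arrays arrive with arbitrary index orientation, so every
#' geometric operation in this package works on a *canonical* orientation:
#' array axis 1 increasing towards anterior, axis 2 increasing towards
#' superior (and, for 3D masks, axis 3 spanning left-right, along which the
#' mid-sagittal slice is taken). An `axis_convention` records how the raw
#' array maps onto that frame.
#'
#' @param anterior,superior Signed axis labels such as `"+1"`, `"-2"`,
#'   `"+3"`: the array dimension (1, 2 or 3) along which the anatomical
#'   direction runs, and whether it runs with (`+`) or against (`-`)
#'   increasing index.
#' @return An object of class `axis_convention`.
#' @examples
#' axis_convention("+1", "+2")          # already canonical
#' axis_convention("-2", "+1")          # columns run posterior-ward
#' @export
axis_convention <- function(anterior = "+1", superior = "+2") {
  a <- parse_axis(anterior, "anterior")
  s <- parse_axis(superior, "superior")
  if (a$axis == s$axis)
    stop("anterior and superior must name different array axes", call. = FALSE)
  structure(list(anterior = a, superior = s), class = "axis_convention")
}

parse_axis <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || !grepl("^[+-][123]$", x))
    stop(sprintf("%s axis must be one of '+1','-1','+2','-2','+3','-3'", what),
         call. = FALSE)
  list(sign = if (substr(x, 1, 1) == "-") -1L else 1L,
       axis = as.integer(substr(x, 2, 2)))
}

#' @export
print.axis_convention <- function(x, ...) {
  fmt <- function(p) sprintf("%s%d", if (p$sign > 0) "+" else "-", p$axis)
  cat("axis convention: anterior = ", fmt(x$anterior),
      ", superior = ", fmt(x$superior), "\n", sep = "")
  invisible(x)
}

# Reorient a 2D slice so that rows run posterior->anterior and columns
# inferior->superior. `conv` must only reference axes 1 and 2.
canonicalize_slice <- function(slice, conv) {
  stopifnot(is.matrix(slice))
  if (conv$anterior$axis > 2L || conv$superior$axis > 2L)
    stop("2D slice convention may only use axes 1 and 2", call. = FALSE)
  if (conv$anterior$axis == 2L) slice <- t(slice)
  if (conv$anterior$sign < 0L)
    slice <- slice[rev(seq_len(nrow(slice))), , drop = FALSE]
  if (conv$superior$sign < 0L)
    slice <- slice[, rev(seq_len(ncol(slice))), drop = FALSE]
  slice
}

# Reorient a 3D array to [anterior, superior, left-right]; returns the array
# plus the permutation applied so spacings and slice indices can follow.
canonicalize_volume <- function(arr, conv) {
  stopifnot(length(dim(arr)) == 3L)
  lr_axis <- setdiff(1:3, c(conv$anterior$axis, conv$superior$axis))
  perm <- c(conv$anterior$axis, conv$superior$axis, lr_axis)
  out <- aperm(arr, perm)
  if (conv$anterior$sign < 0L)
    out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
  if (conv$superior$sign < 0L)
    out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  list(array = out, perm = perm)
}

# Scoped RNG: evaluate expr under a seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
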