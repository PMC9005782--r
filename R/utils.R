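#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Euclidean distance between two 3-vectors
dist3 <- function(a, b) sqrt(sum((a - b)^2))

## Unit-mass centre of mass of an n x 3 coordinate matrix
com3 <- function(xyz) colMeans(xyz)

## Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Element symbol from a PDB atom name (amino-acid atoms only: the element is
## the first alphabetic character, e.g. "OD1" -> "O", "NH2" -> "N").
guess_element <- function(atom_name) {
  sub("^[0-9 ]*([A-Za-z]).*$", "\\1", atom_name)
}

## Random proper rotation (uniform via QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## Apply rigid transform to an n x 3 matrix
apply_transform <- function(xyz, rotation, translation) {
  xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
}

## Minimal assertion helper with informative message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
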