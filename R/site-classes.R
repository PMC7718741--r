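#' Site-class mixtures for the nested codon models
#'
#' Builds the site-class table for each supported model. Every class has a
#' proportion and a (background, foreground) omega pair; a branch of the
#' tree uses the foreground omega when it carries a foreground mark and the
#' background omega otherwise.
#'
#' * `M0`: one class, omega shared by all branches.
#' * `two_ratios`: one class, separate background/foreground omega.
#' * `M1a`: classes `(p0, omega0 < 1)` and `(1 - p0, 1)`, no branch effect.
#' * `M2a`: adds a third class with `omega2 >= 1` on all branches.
#' * `MA`: classes 0 `(p0; omega0, omega0)`, 1 `(p1; 1, 1)`,
#'   2a `(p2a; omega0, omega2)`, 2b `(p2b; 1, omega2)` with
#'   `p2a = (1 - p0 - p1) p0 / (p0 + p1)` and
#'   `p2b = (1 - p0 - p1) p1 / (p0 + p1)`.
#' * `MA_null`: model A with `omega2` fixed at 1.
#'
#' @param model Model identifier.
#' @param omega Single omega (M0) or background omega (two_ratios).
#' @param omegaFg Foreground omega (two_ratios).
#' @param p0,p1 Mixture proportions (model-specific; see details).
#' @param omega0 Purifying-class omega in (0, 1).
#' @param omega2 Positive-class omega >= 1 (M2a, MA).
#' @return Data frame with columns `class`, `prop`, `omegaBg`, `omegaFg`
#'   and attribute `model`.
#' @export
#' @examples
#' siteClassMix("MA", p0 = 0.6, p1 = 0.3, omega0 = 0.1, omega2 = 4)
siteClassMix <- function(model = c("M0", "two_ratios", "M1a", "M2a", "MA_null", "MA"),
                         omega = NULL, omegaFg = NULL, p0 = NULL, p1 = NULL,
                         omega0 = NULL, omega2 = NULL) {
  model <- match.arg(model)
  chk01 <- function(p, nm) {
    if (is.null(p) || p < 0 || p > 1) stop(nm, " must lie in [0,1]")
    p
  }
  mix <- switch(model,
    M0 = {
      stopifnot(!is.null(omega), omega >= 0)
      data.frame(class = "0", prop = 1, omegaBg = omega, omegaFg = omega)
    },
    two_ratios = {
      stopifnot(!is.null(omega), !is.null(omegaFg), omega >= 0, omegaFg >= 0)
      data.frame(class = "0", prop = 1, omegaBg = omega, omegaFg = omegaFg)
    },
    M1a = {
      p0 <- chk01(p0, "p0")
      stopifnot(!is.null(omega0), omega0 >= 0, omega0 < 1)
      data.frame(
        class = c("0", "1"), prop = c(p0, 1 - p0),
        omegaBg = c(omega0, 1), omegaFg = c(omega0, 1)
      )
    },
    M2a = {
      p0 <- chk01(p0, "p0")
      p1 <- chk01(p1, "p1")
      if (p0 + p1 > 1) stop("p0 + p1 must be <= 1")
      stopifnot(!is.null(omega0), omega0 >= 0, omega0 < 1)
      stopifnot(!is.null(omega2), omega2 >= 1)
      data.frame(
        class = c("0", "1", "2"), prop = c(p0, p1, 1 - p0 - p1),
        omegaBg = c(omega0, 1, omega2), omegaFg = c(omega0, 1, omega2)
      )
    },
    MA_null = ,
    MA = {
      p0 <- chk01(p0, "p0")
      p1 <- chk01(p1, "p1")
      if (p0 + p1 > 1) stop("p0 + p1 must be <= 1")
      if (p0 + p1 <= 0) stop("p0 + p1 must be positive under model A")
      stopifnot(!is.null(omega0), omega0 >= 0, omega0 < 1)
      if (model == "MA_null") {
        omega2 <- 1
      } else {
        stopifnot(!is.null(omega2), omega2 >= 1)
      }
      p2 <- 1 - p0 - p1
      data.frame(
        class = c("0", "1", "2a", "2b"),
        prop = c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1)),
        omegaBg = c(omega0, 1, omega0, 1),
        omegaFg = c(omega0, 1, omega2, omega2)
      )
    }
  )
  attr(mix, "model") <- model
  mix
}
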