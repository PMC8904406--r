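#' Per-animal feed dry-matter intake
#'
#' Total feed consumed by one animal over its accounting period (one year for
#' dairy, lifetime-to-slaughter for meat) is the product of the feed
#' conversion ratio and the per-animal product output:
#'
#' \deqn{Feed_{a,s} = FCR_{a,s} \times P_{a,s} / 1000}
#'
#' with FCR in kg feed dry matter per kg product, output in kg product per
#' animal, and the result in tonnes dry matter per animal. The kg-to-tonne
#' conversion happens here and only here.
#'
#' @param fcr feed conversion ratio, kg DM feed per kg product; > 0.
#' @param output product output, kg per animal per accounting period; > 0.
#' @return tonnes dry matter per animal per accounting period. Vectorized
#'   over both arguments.
#' @examples
#' total_feed_intake(fcr = 10, output = 1000) # 10 t DM
#' @export
total_feed_intake <- function(fcr, output) {
  if (any(!is.finite(fcr)) || any(fcr <= 0)) {
    stop("domain error: fcr must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(output)) || any(output <= 0)) {
    stop("domain error: output must be finite and > 0", call. = FALSE)
  }
  fcr * output / 1000
}

#' Allocate total feed intake across the diet basket
#'
#' Splits total dry-matter intake across feed types in proportion to the diet
#' basket of the animal's production system. Allocation conserves dry matter:
#' the per-type amounts sum back to the total.
#'
#' @param total_dm total intake, tonnes DM per animal; >= 0.
#' @param basket named numeric vector of diet fractions by feed type, summing
#'   to 1 (relative tolerance 1e-9), all in \[0, 1\].
#' @return object of class `feed_demand`: a list with `total_dm` and
#'   `by_type` (named numeric, tonnes DM per feed type).
#' @examples
#' allocate_feed(10, c(pasture = 0.5, concentrate = 0.5))
#' @export
allocate_feed <- function(total_dm, basket) {
  if (!is.finite(total_dm) || total_dm < 0) {
    stop("domain error: total_dm must be finite and >= 0", call. = FALSE)
  }
  if (length(basket) > 0 &&
      (is.null(names(basket)) || any(!nzchar(names(basket))))) {
    stop("basket fractions must be named by feed type", call. = FALSE)
  }
  if (any(basket < 0 | basket > 1)) {
    stop("validation error: basket fractions must lie in [0, 1]",
         call. = FALSE)
  }
  if (length(basket) > 0 && !.rel_close(sum(basket), 1)) {
    stop("validation error: basket fractions sum to ",
         format(sum(basket), digits = 12), ", not 1", call. = FALSE)
  }
  by_type <- total_dm * basket
  feed_demand(total_dm = total_dm, by_type = by_type)
}

#' Construct a feed-demand object
#'
#' @param total_dm tonnes DM per animal.
#' @param by_type named numeric vector, tonnes DM per feed type; must sum to
#'   `total_dm` within relative tolerance 1e-9 and be nonnegative.
#' @return object of class `feed_demand`.
#' @export
feed_demand <- function(total_dm, by_type) {
  by_type <- unlist(by_type)
  if (length(by_type) == 0) by_type <- stats::setNames(numeric(0), character(0))
  if (any(by_type < 0) || total_dm < 0) {
    stop("domain error: feed demand components must be >= 0", call. = FALSE)
  }
  if (!.rel_close(sum(by_type), total_dm)) {
    stop("validation error: feed demand by type (sum ",
         format(sum(by_type), digits = 12), ") does not match total_dm (",
         format(total_dm, digits = 12), ")", call. = FALSE)
  }
  structure(list(total_dm = total_dm, by_type = by_type),
            class = "feed_demand")
}

#' @export
print.feed_demand <- function(x, ...) {
  cat("Feed demand:", format(x$total_dm, digits = 6),
      "t DM per animal per period\n")
  if (length(x$by_type) > 0) {
    for (p in names(x$by_type)) {
      cat(sprintf("  %-16s %s t\n", p, format(x$by_type[[p]], digits = 6)))
    }
  }
  invisible(x)
}
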