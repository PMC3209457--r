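#' Hardy-Weinberg frequencies from an allele frequency
#'
#' For an autosomal recessive allele at frequency p under random mating,
#' genotype frequencies are (1-p)^2, 2p(1-p), p^2. Two carrier
#' conventions are offered: `"exact"` uses 2p(1-p); `"rare_approx"` uses
#' the rare-allele shorthand 2p common in clinical genetics (for p =
#' 0.004 it gives the familiar round numbers: carrier 0.8%, i.e. 1 in
#' 125, and affected homozygotes 1 in 62,500). The rare approximation is
#' the default because it is the arithmetic clinical papers print.
#'
#' @param p Allele frequency, in (0, 1).
#' @param convention `"rare_approx"` (carrier = 2p, default) or
#'   `"exact"` (carrier = 2p(1-p)).
#' @return A one-row `hw_result` tibble: `allele_freq`, `carrier_freq`,
#'   `homozygote_freq`, `one_in_n_carrier`, `one_in_n_homozygote`,
#'   `convention`.
#' @examples
#' hw_from_allele_freq(0.004)          # carrier 1:125, homozygote 1:62,500
#' hw_from_allele_freq(0.5, "exact")
#' @export
hw_from_allele_freq <- function(p, convention = c("rare_approx", "exact")) {
  convention <- match.arg(convention)
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1) {
    abort("allele frequency must be a single number in (0, 1)",
          class = "flexmotif_domain_error")
  }
  carrier <- if (convention == "rare_approx") 2 * p else 2 * p * (1 - p)
  homozygote <- p^2
  tibble::new_tibble(
    tibble::tibble(allele_freq = p, carrier_freq = carrier,
                   homozygote_freq = homozygote,
                   one_in_n_carrier = 1 / carrier,
                   one_in_n_homozygote = 1 / homozygote,
                   convention = convention),
    class = "hw_result"
  )
}

#' Hardy-Weinberg frequencies from a carrier frequency
#'
#' Inverts the chosen carrier convention to recover the allele frequency
#' and then proceeds as [hw_from_allele_freq()]. Under `"rare_approx"`,
#' p = carrier/2; under `"exact"`, p is the smaller root of
#' 2p(1-p) = carrier, which requires carrier <= 1/2.
#'
#' @param carrier Carrier (heterozygote) frequency, in (0, 1).
#' @inheritParams hw_from_allele_freq
#' @return A one-row `hw_result` tibble (see [hw_from_allele_freq()]).
#' @examples
#' # carrier 1.35% -> ~1 in 22,000 affected
#' hw_from_carrier_freq(0.0135)
#' @export
hw_from_carrier_freq <- function(carrier, convention = c("rare_approx", "exact")) {
  convention <- match.arg(convention)
  if (!is.numeric(carrier) || length(carrier) != 1 || !is.finite(carrier) ||
      carrier <= 0 || carrier >= 1) {
    abort("carrier frequency must be a single number in (0, 1)",
          class = "flexmotif_domain_error")
  }
  p <- if (convention == "rare_approx") {
    carrier / 2
  } else {
    if (carrier > 0.5) {
      abort("exact convention has no real solution for carrier > 0.5",
            class = "flexmotif_domain_error")
    }
    (1 - sqrt(1 - 2 * carrier)) / 2
  }
  hw_from_allele_freq(p, convention)
}

#' @export
print.hw_result <- function(x, ...) {
  cat(sprintf(
    paste0("# Hardy-Weinberg (%s convention)\n",
           "#   allele frequency     p  = %.6g\n",
           "#   carrier frequency       = %.6g  (1 in %.6g)\n",
           "#   affected homozygotes p2 = %.6g  (1 in %.6g)\n"),
    x$convention, x$allele_freq, x$carrier_freq, x$one_in_n_carrier,
    x$homozygote_freq, x$one_in_n_homozygote))
  invisible(x)
}
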