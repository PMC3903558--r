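# helper: trunk of L walking-leg pairs, then state overrides
.blank_units <- function(L) {
  data.frame(leg_pair = seq_len(L),
             state_left = rep("WALKING_LEG", L),
             state_right = rep("WALKING_LEG", L),
             annotation = rep("", L), stringsAsFactors = FALSE)
}

.set_state <- function(units, positions, state, side = "B", annotation = NULL) {
  sel <- units$leg_pair %in% positions
  if (side %in% c("B", "L")) units$state_left[sel] <- state
  if (side %in% c("B", "R")) units$state_right[sel] <- state
  if (!is.null(annotation)) units$annotation[sel] <- annotation
  units
}

#' Encoded specimens from the homeotic-gonopod literature
#'
#' Returns the six phenotype records the inference layer is exercised on:
#'
#' * `normal_ommatoiulus` — normal *Ommatoiulus moreleti* male: anterior
#'   gonopods at leg pair 8, posterior at 9, both on ring 7.
#' * `homeotic_ommatoiulus` — the homeotic *O. moreleti* male: six extra
#'   pairs of posterior gonopods at leg pairs 10-11 (ring 8), 24-25 (ring
#'   15) and 26-27 (ring 16), besides the normal set on ring 7; one ring
#'   equivalent to rings 13+14 carrying walking-leg pairs 20-23 (fusion);
#'   left antenna atrophied (recorded as provenance); 46 podous rings,
#'   stadium 10. Positions behind pair 27 are walking-leg defaults, flagged
#'   low confidence.
#' * `normal_nannaria` — normal polydesmidan male (*Nannaria conservata*):
#'   one gonopod pair at leg pair 8.
#' * `homeotic_nannaria` — the homeotic *N. conservata* male: extra gonopod
#'   pairs in place of legs 4 and 12, i.e. 4 pairs in front of and 4 behind
#'   the normal pair 8.
#' * `pseudoeurydesmus` — teratological *Pseudoeurydesmus baguassuensis*:
#'   left leg 7 replaced by an extra gonopod, normal gonopod pair 8.
#' * `madeira_ommatoiulus` — teratological *O. moreleti* from Madeira:
#'   normal gonopods at pairs 8-9, an atrophied leg pair 10, and a
#'   malformed posterior gonopod at the level of leg 11.
#'
#' @return Named list of [phenotype()] objects.
#' @examples
#' fx <- fixtures()
#' gonopod_positions(fx$homeotic_ommatoiulus)
#' @export
fixtures <- function() {
  out <- list()

  # --- normal O. moreleti: 46 podous rings -> 3 + 43*2 = 89 leg pairs
  u <- .blank_units(89)
  u <- .set_state(u, 8, "ANTERIOR_GONOPOD")
  u <- .set_state(u, 9, "POSTERIOR_GONOPOD")
  out$normal_ommatoiulus <- phenotype(
    u, "julidan",
    provenance = "normal Ommatoiulus moreleti male; gonopods on ring 7",
    stadium = 10, podous_rings = 46)

  # --- homeotic O. moreleti
  u <- .blank_units(89)
  u <- .set_state(u, 8, "ANTERIOR_GONOPOD")
  u <- .set_state(u, 9, "POSTERIOR_GONOPOD")
  u <- .set_state(u, 10:11, "POSTERIOR_GONOPOD",
                  annotation = "ectopic; distorted, foveae empty")
  u <- .set_state(u, 24:25, "POSTERIOR_GONOPOD",
                  annotation = "ectopic; asymmetric, paracoxites reduced")
  u <- .set_state(u, 26:27, "POSTERIOR_GONOPOD",
                  annotation = "ectopic; solenomerites of last pair highly reduced")
  u$annotation[28:89] <- "default_low_confidence"
  out$homeotic_ommatoiulus <- phenotype(
    u, "julidan",
    ring_map = build_ring_map(89, fusions = list(c(13, 14))),
    provenance = paste("homeotic Ommatoiulus moreleti male with 6 extra pairs",
                       "of posterior gonopods; left antenna atrophied;",
                       "single ring equivalent to rings 13+14"),
    stadium = 10, podous_rings = 46)

  # --- polydesmidans encoded at L = 31 (typical adult trunk)
  u <- .blank_units(31)
  u <- .set_state(u, 8, "GONOPOD_GENERIC")
  out$normal_nannaria <- phenotype(
    u, "polydesmidan",
    provenance = "normal Nannaria conservata male; gonopods at appendage pair 8")

  u <- .blank_units(31)
  u <- .set_state(u, c(4, 8, 12), "GONOPOD_GENERIC")
  u$annotation[u$leg_pair %in% c(4, 12)] <- "ectopic"
  out$homeotic_nannaria <- phenotype(
    u, "polydesmidan",
    provenance = paste("homeotic Nannaria conservata male; extra gonopod",
                       "pairs in place of legs 4 and 12"))

  u <- .blank_units(31)
  u <- .set_state(u, 7, "GONOPOD_GENERIC", side = "L",
                  annotation = "extra gonopod replacing left leg 7")
  u <- .set_state(u, 8, "GONOPOD_GENERIC")
  out$pseudoeurydesmus <- phenotype(
    u, "polydesmidan",
    provenance = "teratological Pseudoeurydesmus baguassuensis male")

  # --- Madeira O. moreleti, encoded to the described anterior region
  u <- .blank_units(27)
  u <- .set_state(u, 8, "ANTERIOR_GONOPOD")
  u <- .set_state(u, 9, "POSTERIOR_GONOPOD")
  u <- .set_state(u, 10, "ATROPHIED_LEG", annotation = "atrophied leg")
  u <- .set_state(u, 11, "POSTERIOR_GONOPOD",
                  annotation = "additional malformed posterior gonopod")
  out$madeira_ommatoiulus <- phenotype(
    u, "julidan",
    provenance = "teratological Ommatoiulus moreleti from Madeira")

  out
}
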