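#' Canonical muscle and marker sets
#'
#' The 13 ipsilateral lower-limb muscles analysed by the pipeline, in the
#' fixed order used by every muscles-by-time matrix: gluteus medius (ME),
#' gluteus maximus (MA), tensor fasciae latae (FL), rectus femoris (RF),
#' vastus medialis (VM), vastus lateralis (VL), semitendinosus (ST),
#' biceps femoris long head (BF), tibialis anterior (TA), peroneus longus
#' (PL), gastrocnemius medialis (GM), gastrocnemius lateralis (GL) and
#' soleus (SO).
#'
#' @return `lunge_muscles()`: character vector of 13 muscle codes.
#' @export
#' @examples
#' lunge_muscles()
lunge_muscles <- function() {
  c("ME", "MA", "FL", "RF", "VM", "VL", "ST",
    "BF", "TA", "PL", "GM", "GL", "SO")
}

#' @rdname lunge_muscles
#' @return `lunge_markers()`: character vector of the marker names the
#'   angle and event algorithms require (greater trochanter, lateral
#'   femoral epicondyle, lateral malleolus, calcaneus, fifth metatarsal
#'   head, toe tip).
#' @export
lunge_markers <- function() {
  c("trochanter", "epicondyle_lat", "malleolus_lat",
    "calcaneus", "metatarsal5", "toe")
}

# number of normalized points per cycle and the swing/stance split
CYCLE_POINTS <- 200L
SWING_POINTS <- 50L
STANCE_POINTS <- 150L

synergy_labels <- function() {
  c("swing", "touchdown", "weight_acceptance", "stabilization")
}
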