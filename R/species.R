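#' Enumerate the species of the Ca2+-CaM-CAMTA binding network
#'
#' Calmodulin (CaM) carries two EF-hand pairs: the N-terminal lobe and the
#' C-terminal lobe, each binding up to two Ca2+ ions sequentially. Every CaM
#' occupancy state exists both free and bound to the transcription factor
#' CAMTA, giving 3 x 3 x 2 = 18 CaM species; free CAMTA is the 19th state
#' variable. Species are named `M{n}{c}` (free CaM with `n` N-lobe and `c`
#' C-lobe Ca2+) or `M{n}{c}X` (the same occupancy bound to CAMTA); free CAMTA
#' is `X`. The fully loaded bound complex `M22X` (4Ca2+-CaM-CAMTA) is the
#' transcriptionally active species.
#'
#' The ordering is fixed and documented so that state vectors and trajectory
#' files are stable: the free layer first (`M00`, `M01`, `M02`, `M10`, ...,
#' `M22`, C-lobe count varying fastest), then the CAMTA-bound layer in the
#' same occupancy order, then `X`.
#'
#' @return A data frame with one row per state variable and columns
#'   `name`, `n_ca` (N-lobe Ca2+ count, `NA` for `X`), `c_ca` (C-lobe count),
#'   `camta_bound` (logical, `NA` for `X`), and `active` (logical; `TRUE`
#'   only for `M22X`).
#' @examples
#' sp <- cam_species()
#' nrow(sp)             # 19
#' sp$name[sp$active]   # "M22X"
#' @export
cam_species <- function() {
  n <- rep(rep(0:2, each = 3), 2)
  c <- rep(rep(0:2, times = 3), 2)
  bound <- rep(c(FALSE, TRUE), each = 9)
  name <- paste0("M", n, c, ifelse(bound, "X", ""))
  sp <- data.frame(
    name = c(name, "X"),
    n_ca = c(n, NA),
    c_ca = c(c, NA),
    camta_bound = c(bound, NA),
    stringsAsFactors = FALSE
  )
  sp$active <- sp$name == "M22X"
  sp
}

# index of a CaM species in the canonical ordering; X is 19
species_index <- function(n, c, bound) 1L + c + 3L * n + 9L * as.integer(bound)

#' @rdname cam_species
#' @format NULL
#' @export
active_species <- function() "M22X"
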