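#' Anchored parameters of the binding network
#'
#' The measured/adjustable parameter subset from which every one of the 33
#' rate constants is derived. Lobe constants are macroscopic sequential
#' dissociation constants: `kc1`/`kc2` for the first/second Ca2+ on the
#' C-terminal lobe, `kn1`/`kn2` for the N-terminal lobe, each with its own
#' on-rate. `kd_camta`/`kon_camta` govern binding of any Ca2+-loaded CaM to
#' CAMTA (assumed equal for all loaded states). Apo-CaM binds CAMTA more
#' weakly by the cooperativity factor `p` (Kd divided by `p` < 1 means a
#' larger Kd, i.e. weaker binding); `q` says how much of that cooperativity
#' is carried by the on-rate (`q = 1`: entirely by the off-rate).
#'
#' @param kc1,kc2 Kd (uM) for the first and second Ca2+ on the C lobe.
#' @param kn1,kn2 Kd (uM) for the first and second Ca2+ on the N lobe.
#' @param kon_c1,kon_c2,kon_n1,kon_n2 On-rates (uM^-1 s^-1) for the four
#'   lobe steps.
#' @param kd_camta Kd (uM) for binding of Ca2+-loaded CaM to CAMTA.
#' @param kon_camta On-rate (uM^-1 s^-1) for that binding (adjustable).
#' @param p Ca-dependent cooperativity of CaM-CAMTA binding, in (0, 1].
#' @param q On-rate share of the cooperativity, > 0.
#' @param cam_total Total CaM concentration (uM).
#' @param camta_total Total CAMTA concentration (uM).
#' @return A list of class `base_parameters`.
#' @seealso [derive_reactions()], [cam_model()]
#' @export
base_parameters <- function(kc1 = 10, kc2 = 0.925, kn1 = 25, kn2 = 5,
                            kon_c1 = 4, kon_c2 = 10, kon_n1 = 100,
                            kon_n2 = 150, kd_camta = 1.2e-3, kon_camta = 1,
                            p = 0.1, q = 1, cam_total = 10,
                            camta_total = 10) {
  base <- list(kc1 = kc1, kc2 = kc2, kn1 = kn1, kn2 = kn2,
               kon_c1 = kon_c1, kon_c2 = kon_c2, kon_n1 = kon_n1,
               kon_n2 = kon_n2, kd_camta = kd_camta, kon_camta = kon_camta,
               p = p, q = q, cam_total = cam_total,
               camta_total = camta_total)
  validate_base_parameters(base)
  class(base) <- "base_parameters"
  base
}

validate_base_parameters <- function(base) {
  num <- vapply(base, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), logical(1))
  if (!all(num))
    stop("all base parameters must be finite numeric scalars; bad: ",
         paste(names(base)[!num], collapse = ", "))
  pos <- unlist(base) > 0
  if (!all(pos))
    stop("all base parameters must be strictly positive; non-positive: ",
         paste(names(base)[!pos], collapse = ", "))
  if (base$p > 1)
    stop("p must lie in (0, 1]: apo-CaM cannot bind CAMTA more tightly ",
         "than Ca2+-loaded CaM (got p = ", base$p, ")")
  invisible(base)
}

# reaction label bookkeeping -------------------------------------------------
#
# Free-layer Ca2+ steps R1-R12 follow the published grouping: first C-lobe
# Ca2+ at N occupancy 0/1/2 = R1/R9/R11, second C-lobe = R2/R10/R12, first
# N-lobe at C occupancy 0/1/2 = R3/R5/R7, second N-lobe = R4/R6/R8. The
# CAMTA-bound layer mirrors it at +20 (R21-R32). CaM-CAMTA association uses
# R15 for apo-CaM and R13/R14/R16-R20/R33 for the eight Ca2+-loaded states
# in canonical occupancy order (the label-to-state mapping for the loaded
# states is a documented convention; all share one Kd so it has no effect
# on the dynamics).
ca_edge_label <- function(lobe, step, other, bound) {
  lab <- if (lobe == "C") {
    if (step == 1) c(1L, 9L, 11L)[other + 1L] else c(2L, 10L, 12L)[other + 1L]
  } else {
    if (step == 1) c(3L, 5L, 7L)[other + 1L] else c(4L, 6L, 8L)[other + 1L]
  }
  paste0("R", lab + if (bound) 20L else 0L)
}

bind_labels <- function() {
  # states in canonical order M00, M01, M02, M10, ..., M22
  c("R15", "R13", "R14", "R16", "R17", "R18", "R19", "R20", "R33")
}

#' Derive all 33 reactions of the network by detailed balance
#'
#' Builds the full reaction table from the anchored parameters. Ca2+ binding
#' at one lobe is independent of the other lobe's occupancy, so the twelve
#' free-layer Ca2+ steps reuse the four lobe constants. All nine CaM-CAMTA
#' association steps share `kd_camta`/`kon_camta`, except apo-CaM, whose
#' Kd is `kd_camta / p` and on-rate `kon_camta / q`. Thermodynamic
#' consistency (the Wegscheider condition: the product of equilibrium
#' constants around any closed cycle equals one) then forces the
#' CAMTA-bound-layer Ca2+ steps to equal their free-layer counterparts,
#' except the two steps leaving the apo-CaM-CAMTA complex, whose Kd is
#' multiplied by `p`. For those two forced steps the on-rate is kept equal
#' to the free-layer value and the off-rate absorbs the change, mirroring
#' the `q = 1` reading that cooperativity acts through the off-rate.
#'
#' @param base A [base_parameters()] object (or plain list with the same
#'   fields).
#' @return A data frame with 33 rows and columns `id`, `type`
#'   (`"ca"`/`"bind"`), `from`, `to` (species names; for `"bind"` rows
#'   `from` is the free CaM species and the CAMTA ligand is implicit),
#'   `ligand`, `kd`, `kon`, `koff` (uM, uM^-1 s^-1, s^-1).
#' @examples
#' rx <- derive_reactions(base_parameters())
#' subset(rx, id == "R15")$kd    # 1.2e-3 / 0.1 = 0.012
#' subset(rx, id == "R23")$kd    # 25 * 0.1 = 2.5
#' @export
derive_reactions <- function(base) {
  validate_base_parameters(base)
  rows <- list()
  add <- function(id, type, from, to, ligand, kd, kon) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, type = type, from = from, to = to, ligand = ligand,
      kd = kd, kon = kon, koff = kd * kon, stringsAsFactors = FALSE)
  }
  for (bound in c(FALSE, TRUE)) {
    suff <- if (bound) "X" else ""
    for (n in 0:2) for (c in 0:2) {
      from <- paste0("M", n, c, suff)
      if (n < 2) {
        kd <- if (n == 0) base$kn1 else base$kn2
        kon <- if (n == 0) base$kon_n1 else base$kon_n2
        if (bound && n == 0 && c == 0) kd <- kd * base$p  # forced by detailed balance
        add(ca_edge_label("N", n + 1L, c, bound), "ca", from,
            paste0("M", n + 1L, c, suff), "Ca", kd, kon)
      }
      if (c < 2) {
        kd <- if (c == 0) base$kc1 else base$kc2
        kon <- if (c == 0) base$kon_c1 else base$kon_c2
        if (bound && n == 0 && c == 0) kd <- kd * base$p
        add(ca_edge_label("C", c + 1L, n, bound), "ca", from,
            paste0("M", n, c + 1L, suff), "Ca", kd, kon)
      }
    }
  }
  labs <- bind_labels()
  i <- 0L
  for (n in 0:2) for (c in 0:2) {
    i <- i + 1L
    apo <- n == 0 && c == 0
    kd <- if (apo) base$kd_camta / base$p else base$kd_camta
    kon <- if (apo) base$kon_camta / base$q else base$kon_camta
    add(labs[i], "bind", paste0("M", n, c), paste0("M", n, c, "X"),
        "CAMTA", kd, kon)
  }
  rx <- do.call(rbind, rows)
  rownames(rx) <- NULL
  rx
}

#' Check thermodynamic consistency of a reaction table
#'
#' Verifies the Wegscheider condition on every elementary square cycle of
#' the binding lattice: (i) each free-layer Ca2+ step paired with its
#' CAMTA-bound counterpart and the two flanking CaM-CAMTA association steps
#' (12 cycles), and (ii) the N-step-then-C-step versus C-step-then-N-step
#' squares inside each layer (8 cycles). For a consistent network the
#' product of equilibrium constants around each cycle equals one.
#'
#' @param reactions A reaction table from [derive_reactions()] (possibly
#'   perturbed).
#' @param rel_tol Relative tolerance on `|product - 1|`.
#' @return A data frame with one row per cycle (`cycle`, `description`,
#'   `product`, `pass`) with attribute `ok` (`TRUE` if all cycles pass).
#'   Malformed networks (missing species or edges) raise an error naming
#'   the gap.
#' @examples
#' chk <- wegscheider_check(derive_reactions(base_parameters()))
#' attr(chk, "ok")   # TRUE
#' @export
wegscheider_check <- function(reactions, rel_tol = 1e-9) {
  need <- cam_species()$name
  seen <- unique(c(reactions$from, reactions$to,
                   ifelse(reactions$type == "bind", "X", NA)))
  missing <- setdiff(setdiff(need, "X"), c(reactions$from, reactions$to))
  if (length(missing))
    stop("malformed network: species never touched by any reaction: ",
         paste(missing, collapse = ", "))

  kd_of <- function(from, to) {
    hit <- reactions$kd[reactions$from == from & reactions$to == to]
    if (length(hit) != 1)
      stop("malformed network: expected exactly one reaction ", from,
           " -> ", to, ", found ", length(hit))
    hit
  }
  out <- list()
  push <- function(desc, prod) {
    out[[length(out) + 1L]] <<- data.frame(
      cycle = length(out) + 1L, description = desc, product = prod,
      pass = abs(prod - 1) <= rel_tol, stringsAsFactors = FALSE)
  }
  # (i) binding x Ca squares: Kd(free step) * Kd(bind at product) must equal
  #     Kd(bind at reactant) * Kd(bound step)
  free_ca <- reactions[reactions$type == "ca" & !grepl("X", reactions$from), ]
  for (k in seq_len(nrow(free_ca))) {
    s1 <- free_ca$from[k]; s2 <- free_ca$to[k]
    prod <- (free_ca$kd[k] * kd_of(s2, paste0(s2, "X"))) /
      (kd_of(s1, paste0(s1, "X")) * kd_of(paste0(s1, "X"), paste0(s2, "X")))
    push(paste0("bind/Ca square at ", s1, "->", s2), prod)
  }
  # (ii) lobe-order squares inside each layer
  for (suff in c("", "X")) for (n in 0:1) for (c in 0:1) {
    a <- paste0("M", n, c, suff);      b <- paste0("M", n + 1L, c, suff)
    d <- paste0("M", n, c + 1L, suff); e <- paste0("M", n + 1L, c + 1L, suff)
    prod <- (kd_of(a, b) * kd_of(b, e)) / (kd_of(a, d) * kd_of(d, e))
    push(paste0("lobe square at ", a, " (", if (suff == "X") "bound" else "free",
                " layer)"), prod)
  }
  res <- do.call(rbind, out)
  attr(res, "ok") <- all(res$pass)
  res
}
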