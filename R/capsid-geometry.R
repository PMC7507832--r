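# Closed-form arithmetic of quasi-equivalent icosahedral capsid lattices.
# A capsid built from a hexagonal lattice of trimeric double-jelly-roll
# capsomers is indexed by two lattice steps (h, k) between neighbouring
# fivefold vertices; the triangulation number T = h^2 + hk + k^2 counts
# jelly-roll subunits per icosahedral asymmetric unit.

#' Number of hexameric capsomers in each pentasymmetron
#'
#' Pentagonal patches of identically oriented capsomers around each fivefold
#' vertex contain 30 pseudo-hexameric (trimeric) capsomers plus the single
#' pentameric capsomer at the vertex itself; this count is conserved across
#' icosahedral giant viruses and is therefore a constant, not a parameter.
#' @export
PENTASYMMETRON_HEXAMERS <- 30L

#' Single-jelly-roll penton protein copies per capsid
#'
#' Each of the 12 fivefold vertices carries a pentameric capsomer of five
#' single-jelly-roll subunits, so every icosahedral capsid has 60 penton
#' protein copies.
#' @export
PENTON_PROTEIN_COPIES <- 60L

#' Lattice indices of an icosahedral capsid
#'
#' Validates and canonicalizes the pair of capsomer lattice steps `(h, k)`.
#' The triangulation number is invariant under swapping `h` and `k` (and
#' under the lattice's chiral reflection, which is not modelled), so the
#' canonical form stores `h <= k`.
#'
#' @param h,k Non-negative integer lattice steps; not both zero.
#' @return An object of class `lattice_indices`: a list with elements `h`
#'   and `k` (integers, `h <= k`).
#' @examples
#' lattice_indices(8, 7)  # canonicalized to h = 7, k = 8
#' @export
lattice_indices <- function(h, k) {
  if (length(h) != 1L || length(k) != 1L || is.na(h) || is.na(k)) {
    stop("h and k must be single non-missing values", call. = FALSE)
  }
  if (h < 0 || k < 0 || h != as.integer(h) || k != as.integer(k)) {
    stop("h and k must be non-negative integers", call. = FALSE)
  }
  h <- as.integer(h)
  k <- as.integer(k)
  if (h == 0L && k == 0L) {
    stop("invalid lattice: h and k cannot both be zero", call. = FALSE)
  }
  if (h > k) {
    tmp <- h
    h <- k
    k <- tmp
  }
  structure(list(h = h, k = k), class = "lattice_indices")
}

#' @export
print.lattice_indices <- function(x, ...) {
  cat(sprintf("icosahedral lattice indices (h = %d, k = %d)\n", x$h, x$k))
  invisible(x)
}

as_lattice_indices <- function(h, k = NULL) {
  if (inherits(h, "lattice_indices")) return(h)
  if (is.null(k) && length(h) == 2L) return(lattice_indices(h[[1L]], h[[2L]]))
  lattice_indices(h, k)
}

#' Triangulation number of an icosahedral lattice
#'
#' Computes `T = h^2 + h*k + k^2`, the quasi-equivalence index counting
#' jelly-roll subunits per 60-fold asymmetric unit.
#'
#' @param h A `lattice_indices` object, a length-2 vector `c(h, k)`, or the
#'   `h` step alone.
#' @param k The `k` step when `h` is given as a scalar.
#' @return The integer triangulation number, `>= 1`.
#' @examples
#' triangulation_number(7, 8)   # 169
#' triangulation_number(7, 18)  # 499
#' @export
triangulation_number <- function(h, k = NULL) {
  idx <- as_lattice_indices(h, k)
  as.integer(idx$h^2 + idx$h * idx$k + idx$k^2)
}

#' Copy-number budget of an icosahedral capsid from its lattice indices
#'
#' Derives the full per-particle protein budget implied by a triangulation
#' number T: `60*T` jelly rolls in total, of which 60 are the single
#' jelly rolls of the 12 pentameric vertex capsomers and `60*(T-1)` come
#' from `10*(T-1)` pseudo-hexameric trimeric capsomers, i.e. `30*(T-1)`
#' copies of the double-jelly-roll major capsid protein (MCP). The
#' hexameric capsomers decompose into 12 pentasymmetrons of
#' [PENTASYMMETRON_HEXAMERS] capsomers each plus 20 trisymmetrons; the
#' trisymmetron size must come out a non-negative integer or the lattice is
#' inconsistent with that decomposition.
#'
#' @inheritParams triangulation_number
#' @return An object of class `capsid_architecture`: a list with elements
#'   `h`, `k`, `t_number`, `jelly_rolls_total`, `hexameric_capsomers`,
#'   `pentameric_capsomers`, `mcp_copies`, `penton_protein_copies`,
#'   `trisymmetron_capsomers`, `pentasymmetron_hexamers`.
#' @examples
#' capsid_architecture(7, 8)  # T = 169, 5040 MCP copies, 66-capsomer trisymmetrons
#' @export
capsid_architecture <- function(h, k = NULL) {
  idx <- as_lattice_indices(h, k)
  t_num <- triangulation_number(idx)
  hexamers <- 10L * (t_num - 1L)
  tri_raw <- hexamers - 12L * PENTASYMMETRON_HEXAMERS
  if (tri_raw < 0L || tri_raw %% 20L != 0L) {
    stop(sprintf(
      paste0("symmetron decomposition error: %d hexameric capsomers cannot ",
             "be split into 12 pentasymmetrons of %d plus 20 equal ",
             "trisymmetrons"),
      hexamers, PENTASYMMETRON_HEXAMERS), call. = FALSE)
  }
  structure(list(
    h = idx$h,
    k = idx$k,
    t_number = t_num,
    jelly_rolls_total = 60L * t_num,
    hexameric_capsomers = hexamers,
    pentameric_capsomers = 12L,
    mcp_copies = 3L * hexamers,
    penton_protein_copies = PENTON_PROTEIN_COPIES,
    trisymmetron_capsomers = tri_raw %/% 20L,
    pentasymmetron_hexamers = PENTASYMMETRON_HEXAMERS
  ), class = "capsid_architecture")
}

#' @export
print.capsid_architecture <- function(x, ...) {
  cat("Icosahedral capsid architecture\n")
  cat(sprintf("  lattice indices          h = %d, k = %d\n", x$h, x$k))
  cat(sprintf("  triangulation number     T = %d\n", x$t_number))
  cat(sprintf("  jelly rolls (total)      %d\n", x$jelly_rolls_total))
  cat(sprintf("  hexameric capsomers      %d (trimeric, pseudo-hexameric)\n",
              x$hexameric_capsomers))
  cat(sprintf("  pentameric capsomers     %d\n", x$pentameric_capsomers))
  cat(sprintf("  MCP copies               %d (double jelly roll)\n",
              x$mcp_copies))
  cat(sprintf("  penton protein copies    %d (single jelly roll)\n",
              x$penton_protein_copies))
  cat(sprintf("  trisymmetron             %d capsomers x 20\n",
              x$trisymmetron_capsomers))
  cat(sprintf("  pentasymmetron           %d hexamers + 1 pentamer, x 12\n",
              x$pentasymmetron_hexamers))
  invisible(x)
}

#' @param x A `capsid_architecture` object.
#' @param row.names,optional,... Passed on conventionally; unused.
#' @rdname capsid_architecture
#' @export
as.data.frame.capsid_architecture <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  data.frame(
    h = x$h, k = x$k, t_number = x$t_number,
    capsomers = x$hexameric_capsomers,
    mcp_copies = x$mcp_copies,
    jelly_rolls_total = x$jelly_rolls_total,
    trisymmetron_capsomers = x$trisymmetron_capsomers,
    stringsAsFactors = FALSE
  )
}

#' Enumerate lattice indices compatible with a triangulation number
#'
#' Brute-force enumeration of all canonical pairs `h <= k` with
#' `h^2 + h*k + k^2 == t_number`. Optionally restricted to pairs containing
#' a fixed step (the `h = 7` step is conserved across icosahedral giant
#' viruses, so recovering `k` from an observed T with `h_fixed = 7` is the
#' common use).
#'
#' @param t_number Target triangulation number, `>= 1`.
#' @param h_fixed Optional integer; keep only pairs with this value in
#'   either slot.
#' @return A list of `lattice_indices`, sorted by `h`; empty when no
#'   solution exists.
#' @examples
#' hk_candidates_from_T(169)              # (0,13) and (7,8)
#' hk_candidates_from_T(219, h_fixed = 7) # (7,10)
#' @export
hk_candidates_from_T <- function(t_number, h_fixed = NULL) {
  if (length(t_number) != 1L || is.na(t_number) || t_number < 1 ||
      t_number != as.integer(t_number)) {
    stop("t_number must be a single integer >= 1", call. = FALSE)
  }
  t_number <- as.integer(t_number)
  kmax <- as.integer(ceiling(sqrt(t_number)))
  out <- list()
  for (h in 0:kmax) {
    for (k in h:kmax) {
      if (h == 0L && k == 0L) next
      if (h * h + h * k + k * k == t_number) {
        out[[length(out) + 1L]] <- lattice_indices(h, k)
      }
    }
  }
  if (!is.null(h_fixed)) {
    keep <- vapply(out, function(p) p$h == h_fixed || p$k == h_fixed,
                   logical(1))
    out <- out[keep]
  }
  out[order(vapply(out, `[[`, integer(1), "h"))]
}
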