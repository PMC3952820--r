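#' Default synthetic compound set
#'
#' Three compounds spanning the modeled kinetic behaviors, with synthetic
#' default parameters (plausible orders of magnitude for small lipophilic
#' molecules; not literature values, all overridable):
#' * `tracer` — an inert lipophilic dye: passive exchange only.
#' * `lindrug` — a linearly cleared drug (first-order cellular
#'   metabolization).
#' * `mmdrug` — a high-clearance drug with Michaelis-Menten cellular
#'   metabolization.
#'
#' @param name one of `"tracer"`, `"lindrug"`, `"mmdrug"`.
#' @return a [compound_params()].
#' @export
default_compound <- function(name = c("tracer", "lindrug", "mmdrug")) {
  name <- match.arg(name)
  # equilibria: c_rbc = K_bp c_pls, c_pls = K_pi c_int, c_cell = K_cell c_int
  ifc <- function(K_cell) data.frame(
    a = c("rbc", "pls", "cell"), b = c("pls", "int", "int"),
    K = c(0.8, 1.0, K_cell), P = c(30, 20, 10) # 1/min
  )
  switch(name,
    tracer = compound_params("tracer", MW = 557, logP = 3.0, fu = 0.9,
      interfaces = ifc(K_cell = 4), k_lip = 40,
      metabolism = metabolism_params("none")),
    lindrug = compound_params("lindrug", MW = 326, logP = 2.5, fu = 0.6,
      interfaces = ifc(K_cell = 3), k_lip = 30,
      metabolism = metabolism_params("linear", k_met = 1.5)),
    mmdrug = compound_params("mmdrug", MW = 420, logP = 3.5, fu = 0.4,
      interfaces = ifc(K_cell = 5), k_lip = 50,
      metabolism = metabolism_params("michaelis_menten", V_max = 60, K_m = 15))
  )
}

#' Default subspace volume fractions
#'
#' Synthetic mouse-liver defaults (vascular/rest fraction plus PK-Sim-style
#' subcompartment proportions rescaled to sum to one).
#' @export
default_fractions <- function() {
  c(rbc = 0.062, pls = 0.098, int = 0.163, cell = 0.577, rest = 0.1)
}

#' Read / write compound parameters as YAML or JSON
#'
#' Flat key-value schema: `name`, `MW`, `logP`, `fu`, `k_lip`,
#' `interfaces` (list of `a`, `b`, `K`, `P`), `metabolism`
#' (`mode`, `k_met`/`V_max`/`K_m`).
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @export
read_compound <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  ifc <- doc$interfaces
  if (!is.data.frame(ifc)) {
    ifc <- if (all(c("a", "b", "K", "P") %in% names(ifc))) {
      as.data.frame(ifc) # column-wise map (YAML)
    } else {
      do.call(rbind, lapply(ifc, as.data.frame)) # list of rows (JSON)
    }
  }
  met <- doc$metabolism
  compound_params(doc$name, doc$MW, doc$logP, doc$fu, ifc,
    k_lip = if (is.null(doc$k_lip)) 0 else doc$k_lip,
    metabolism = metabolism_params(met$mode, k_met = met$k_met,
      V_max = met$V_max, K_m = met$K_m))
}

#' @rdname read_compound
#' @param compound a [compound_params()].
#' @export
write_compound <- function(compound, path) {
  doc <- list(name = compound$name, MW = compound$MW, logP = compound$logP,
    fu = compound$fu, k_lip = compound$k_lip,
    interfaces = compound$interfaces,
    metabolism = compound$metabolism[!vapply(compound$metabolism, is.null,
      logical(1))])
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(doc, path)
  else jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# package-level cache for expensive deterministic fixtures
.fixture_cache <- new.env(parent = emptyenv())

#' The standard desk-scale fixture
#'
#' A deterministic, fully synthetic substrate for tests and examples: a
#' two-lobe ellipsoidal mask at 32^3 scale, supplying and draining trees
#' grown by constrained constructive optimization to 64 terminals each (from
#' single root edges entering at opposite poles), flows assigned at
#' `Q_liv`, short edges pruned at the grid resolution. A desk-scale analogue
#' of a production-resolution liver setup; all geometry invariants hold by
#' construction.
#'
#' @param Q_liv total perfusion (mm^3/s).
#' @param n_leaves terminals per tree.
#' @param spacing grid spacing (mm).
#' @param seed base RNG seed (the trees use `seed` and `seed + 1`).
#' @param cache reuse a previously built identical fixture from the
#'   in-session cache.
#' @return list: `mask`, `svs`, `dvs`, `Q_liv`, `fractions`, `compounds`
#'   (the three defaults).
#' @export
standard_fixture <- function(Q_liv = 30, n_leaves = 64L, spacing = 0.5,
                             seed = 1L, cache = TRUE) {
  key <- sprintf("std_%g_%d_%g_%d", Q_liv, n_leaves, spacing, seed)
  if (cache && !is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  mask <- generate_synthetic_mask(c(8, 6, 4), spacing,
    lobe_split_plane = list(axis = 1, offset = -2.5), seed = seed)
  ctr <- mask$dim / 2 * spacing
  seed_tree <- function(kind, from, to) {
    vascular_tree(kind, rbind(from, to),
      data.frame(parent = 1L, child = 2L, radius = 0.5))
  }
  svs0 <- seed_tree("supplying", c(ctr[1] - 6.5, ctr[2], ctr[3]),
    c(ctr[1] - 4.5, ctr[2], ctr[3]))
  dvs0 <- seed_tree("draining", c(ctr[1] + 6.5, ctr[2], ctr[3]),
    c(ctr[1] + 4.5, ctr[2], ctr[3]))
  svs <- cco_extend(svs0, mask, n_leaves, seed = seed, r_leaf = 0.15)
  dvs <- cco_extend(dvs0, mask, n_leaves, seed = seed + 1L, r_leaf = 0.15)
  svs <- prune_and_contract(assign_flows(svs, Q_liv), min_length = spacing)
  dvs <- prune_and_contract(assign_flows(dvs, Q_liv), min_length = spacing)
  fx <- list(mask = mask, svs = svs, dvs = dvs, Q_liv = Q_liv,
    fractions = default_fractions(),
    compounds = list(tracer = default_compound("tracer"),
      lindrug = default_compound("lindrug"),
      mmdrug = default_compound("mmdrug")))
  if (cache) .fixture_cache[[key]] <- fx
  fx
}
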