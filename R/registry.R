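# Architecture registry: the twelve circuit architectures A-L, their edges,
# either-sign designations, and the expansion into 84 model variants.
#
# The per-architecture edge lists are reconstructed from the published
# high-level descriptions and the surviving hard constraints (84 variants in
# total; 32 for architecture A; 8 for architecture L, four per sign of its
# fast 5-HT -> DA link; only A and L carry the inhibitory VTA GABA -> DRN
# GABA edge; architecture K is the minimal template circuit). Integrity of
# those counts is enforced by the test suite.

.pops <- c("HT5_DRN", "DA_VTA", "GLU_DRN", "GABA_DRN", "GABA_VTA")

# Edges that are never considered (limited experimental support).
.forbidden_edges <- data.frame(
  source = c("GABA_DRN", "GABA_DRN", "GABA_VTA", "GLU_DRN", "GABA_DRN", "DA_VTA",
             "GLU_DRN"),
  target = c("DA_VTA", "GABA_VTA", "GLU_DRN", "GABA_DRN", "GLU_DRN", "GLU_DRN",
             "GABA_VTA")
)

#' Catalog of admissible circuit connections
#'
#' All directed connections the model family may contain, one row per edge:
#' the fixed self-connections and autoreceptors, the fast (quasi-steady
#' ionotropic) synaptic links from the glutamate and GABA pools, and the slow
#' sigmoidal neuromodulator-induced links from the 5-HT and DA populations.
#' `sign` is `+1` (excitatory), `-1` (inhibitory) or `NA` for edges whose sign
#' is an architecture-level choice. `d2` marks connections carried by D2
#' receptors (all connections emanating from VTA DA neurons, including the
#' autoreceptor).
#'
#' @return Data frame with columns `name`, `source`, `target`, `mechanism`
#'   (`"fast"` or `"slow"`), `sign`, `d2`.
#' @export
edge_catalog <- function() {
  e <- rbind(
    data.frame(name = "auto_5ht",   source = "HT5_DRN",  target = "HT5_DRN",  mechanism = "slow", sign = -1),
    data.frame(name = "auto_da",    source = "DA_VTA",   target = "DA_VTA",   mechanism = "slow", sign = -1),
    data.frame(name = "self_glu",   source = "GLU_DRN",  target = "GLU_DRN",  mechanism = "fast", sign = +1),
    data.frame(name = "self_gd",    source = "GABA_DRN", target = "GABA_DRN", mechanism = "fast", sign = -1),
    data.frame(name = "self_gv",    source = "GABA_VTA", target = "GABA_VTA", mechanism = "fast", sign = -1),
    data.frame(name = "glu_5ht",    source = "GLU_DRN",  target = "HT5_DRN",  mechanism = "fast", sign = +1),
    data.frame(name = "glu_da",     source = "GLU_DRN",  target = "DA_VTA",   mechanism = "fast", sign = +1),
    data.frame(name = "gv_da",      source = "GABA_VTA", target = "DA_VTA",   mechanism = "fast", sign = -1),
    data.frame(name = "gv_5ht",     source = "GABA_VTA", target = "HT5_DRN",  mechanism = "fast", sign = -1),
    data.frame(name = "gv_gd",      source = "GABA_VTA", target = "GABA_DRN", mechanism = "fast", sign = -1),
    data.frame(name = "gd_5ht",     source = "GABA_DRN", target = "HT5_DRN",  mechanism = "fast", sign = -1),
    data.frame(name = "ht5_gv",     source = "HT5_DRN",  target = "GABA_VTA", mechanism = "slow", sign = +1),
    data.frame(name = "ht5_gd",     source = "HT5_DRN",  target = "GABA_DRN", mechanism = "slow", sign = NA),
    data.frame(name = "ht5_glu",    source = "HT5_DRN",  target = "GLU_DRN",  mechanism = "slow", sign = NA),
    data.frame(name = "ht5_da",     source = "HT5_DRN",  target = "DA_VTA",   mechanism = "slow", sign = NA),
    data.frame(name = "ht5_da_fast", source = "HT5_DRN", target = "DA_VTA",   mechanism = "fast", sign = NA),
    data.frame(name = "da_5ht",     source = "DA_VTA",   target = "HT5_DRN",  mechanism = "slow", sign = +1),
    data.frame(name = "da_gd",      source = "DA_VTA",   target = "GABA_DRN", mechanism = "slow", sign = +1),
    data.frame(name = "da_gv",      source = "DA_VTA",   target = "GABA_VTA", mechanism = "slow", sign = NA)
  )
  e$d2 <- e$source == "DA_VTA"
  rownames(e) <- e$name
  e
}

# Fixed weights that are not solved by the baseline calibration.
# Self-connection couplings are 0.5 (Glu), 0.5 (DRN GABA) and 10 (VTA GABA);
# the DA autoreceptor weight is fixed at 1 (the 5-HT autoreceptor weight is
# calibrated). Remaining entries are fixture weights for the optional edges;
# the DA-sourced (D2) weights are sized so that the simulated-agonist screen
# reproduces the published dose narrative (see the methods vignette).
.fixed_weights <- c(
  auto_da = 1,
  self_glu = 0.5, self_gd = 0.5, self_gv = 10,
  gd_5ht = 0.05, gv_5ht = 0.05,
  ht5_glu = 200, ht5_da = 100, ht5_da_fast = 1,
  ht5_gd_exc = 100,
  da_5ht_A = 150, da_5ht_DEHL = 60, da_5ht_BC = 10,
  da_gd_A = 480, da_gd_G = 50,
  da_gv = 190
)

# Architecture definitions. `edges` lists the optional edges beyond the core
# template set; `either` names the edges whose sign is expanded; `fixed_signs`
# overrides the sign of otherwise either-sign catalog edges.
.core_edges <- c("auto_5ht", "auto_da", "self_glu", "self_gd", "self_gv",
                 "glu_5ht", "glu_da", "gv_da", "ht5_gv", "ht5_gd")

.arch_defs <- function() {
  list(
    A = list(extra = c("ht5_da", "ht5_glu", "da_5ht", "da_gd", "da_gv",
                       "gd_5ht", "gv_5ht", "gv_gd"),
             either = c("ht5_gd", "ht5_da", "ht5_glu", "da_gv"),
             fixed_signs = c(),
             extra_reward_inhibition = TRUE),
    B = list(extra = c("ht5_da", "ht5_glu", "da_5ht", "da_gv", "gd_5ht"),
             either = c("ht5_da", "ht5_glu", "da_gv"),
             fixed_signs = c(ht5_gd = -1)),
    C = list(extra = c("ht5_da", "ht5_glu", "da_5ht", "da_gv", "gd_5ht"),
             either = c("ht5_da", "ht5_glu"),
             fixed_signs = c(da_gv = +1),
             drop = "ht5_gd",
             gd_compensation = TRUE),
    D = list(extra = c("ht5_da", "da_5ht", "gd_5ht"),
             either = "ht5_da",
             fixed_signs = c(ht5_gd = -1)),
    E = list(extra = c("ht5_glu", "da_5ht", "gd_5ht"),
             either = "ht5_glu",
             fixed_signs = c(ht5_gd = -1)),
    F = list(extra = "gd_5ht", either = character(), fixed_signs = c(ht5_gd = -1)),
    G = list(extra = "da_gd", either = character(), fixed_signs = c(ht5_gd = -1)),
    H = list(extra = "da_5ht", either = character(), fixed_signs = c(ht5_gd = -1)),
    I = list(extra = "ht5_da", either = character(),
             fixed_signs = c(ht5_gd = -1, ht5_da = -1)),
    J = list(extra = "gv_5ht", either = character(), fixed_signs = c(ht5_gd = -1)),
    K = list(extra = character(), either = character(), fixed_signs = c(ht5_gd = -1)),
    L = list(extra = c("ht5_da_fast", "ht5_glu", "da_5ht", "da_gv", "gv_gd"),
             either = c("ht5_da_fast", "ht5_glu"),
             fixed_signs = c(ht5_gd = -1, da_gv = +1),
             extra_reward_inhibition = TRUE)
  )
}

#' Architecture identifiers
#' @return Character vector `c("A", ..., "L")`, ordered by decreasing
#'   connectivity (K is the minimal template circuit; L carries the fast
#'   5-HT to DA link).
#' @export
architecture_ids <- function() names(.arch_defs())

#' Architecture specification
#'
#' Assembles the edge table of one architecture: the core template edges plus
#' the architecture's additional connections, with fixed or either ("?") sign
#' designations and D2 tags.
#'
#' @param id One of `architecture_ids()`.
#' @return Object of class `drnvta_architecture`: list with elements `id`,
#'   `edges` (data frame), `either` (edge names whose sign is expanded),
#'   `extra_reward_inhibition`, `gd_compensation`.
#' @export
architecture <- function(id) {
  defs <- .arch_defs()
  if (!id %in% names(defs)) stop("unknown architecture id: ", id)
  d <- defs[[id]]
  core <- setdiff(.core_edges, if (is.null(d$drop)) character() else d$drop)
  nm <- c(core, d$extra)
  cat <- edge_catalog()
  edges <- cat[nm, ]
  for (e in names(d$fixed_signs)) {
    if (e %in% edges$name) edges[e, "sign"] <- d$fixed_signs[[e]]
  }
  edges$either <- edges$name %in% d$either
  # sanity: an either edge must have an undetermined catalog sign
  stopifnot(all(is.na(cat[d$either, "sign"])))
  structure(list(
    id = id,
    edges = edges,
    either = d$either,
    extra_reward_inhibition = isTRUE(d$extra_reward_inhibition),
    gd_compensation = isTRUE(d$gd_compensation)
  ), class = "drnvta_architecture")
}

#' Validate an architecture specification
#'
#' Checks an architecture (or any object with an `edges` data frame) against
#' the admissibility rules: no forbidden connection, all mandatory
#' self-connections present with their fixed couplings, every edge drawn from
#' the catalog, and no negative weight if weights are attached.
#'
#' @param spec A `drnvta_architecture` or a list with an `edges` data frame
#'   (columns `source`, `target`, optionally `name`, `weight`).
#' @return Character vector of violations; empty (length 0) when the
#'   specification is admissible.
#' @export
validate_architecture <- function(spec) {
  edges <- spec$edges
  v <- character()
  fb <- .forbidden_edges
  for (i in seq_len(nrow(fb))) {
    hit <- edges$source == fb$source[i] & edges$target == fb$target[i]
    if (any(hit)) {
      v <- c(v, sprintf("forbidden connection %s -> %s", fb$source[i], fb$target[i]))
    }
  }
  for (s in c("self_glu", "self_gd", "self_gv")) {
    if (!is.null(edges$name) && !s %in% edges$name) {
      v <- c(v, sprintf("missing mandatory self-connection %s", s))
    }
  }
  if (!is.null(edges$name)) {
    unknown <- setdiff(edges$name, edge_catalog()$name)
    if (length(unknown) > 0) {
      v <- c(v, sprintf("edge not in catalog: %s", paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(edges$weight) && any(edges$weight < 0, na.rm = TRUE)) {
    v <- c(v, "negative connection weight")
  }
  v
}

#' Enumerate the calibrated model variants
#'
#' Expands every architecture over its either-sign edges and the two 5-HT
#' neuron types (Type I / Type II) and calibrates each variant's connection
#' weights so that its tonic fixed points reproduce the reference baseline
#' firing rates (see `baseline_targets()` and `calibrate_baseline()`). With
#' the shipped registry this yields 84 variants, numbered deterministically
#' (architecture A first; architecture L last, variants 77-84).
#'
#' @param arch Optional architecture id (or vector of ids) to restrict to.
#' @return List of `drnvta_variant` objects.
#' @export
enumerate_variants <- function(arch = NULL) {
  ids <- if (is.null(arch)) architecture_ids() else arch
  out <- list()
  idx <- 0
  for (id in architecture_ids()) {
    a <- architecture(id)
    ne <- length(a$either)
    signs_grid <- if (ne == 0) {
      list(setNames(numeric(0), character(0)))
    } else {
      g <- expand.grid(rep(list(c(+1, -1)), ne))
      lapply(seq_len(nrow(g)), function(i) setNames(as.numeric(g[i, ]), a$either))
    }
    for (type in c("I", "II")) {
      for (sg in signs_grid) {
        idx <- idx + 1
        if (!id %in% ids) next
        out[[length(out) + 1]] <- .build_variant(a, type, sg, idx)
      }
    }
  }
  out
}

# Construct and calibrate one variant.
.build_variant <- function(arch, type, signs, index) {
  edges <- arch$edges
  for (e in names(signs)) edges[e, "sign"] <- signs[[e]]
  stopifnot(!anyNA(edges$sign))
  edges$weight <- .default_weight(edges$name, edges$sign, arch$id)
  v <- structure(list(
    index = index,
    architecture = arch$id,
    serotonin_type = type,
    signs = signs,
    edges = edges,
    extra_flag = arch$extra_reward_inhibition,
    extra_reward_inhibition = 0,
    gd_compensation = if (arch$gd_compensation) c(constant = NA_real_,
                                                  reward = NA_real_,
                                                  cue_type2 = NA_real_) else NULL
  ), class = "drnvta_variant")
  calibrate_baseline(v)
}

# Fixture weight lookup for edges that the baseline calibration does not
# solve. Solved edges get NA here and are filled in by the calibration.
.default_weight <- function(name, sign, arch_id) {
  fw <- .fixed_weights
  w <- rep(NA_real_, length(name))
  for (i in seq_along(name)) {
    n <- name[i]
    w[i] <- switch(n,
      auto_5ht = NA_real_,            # calibrated
      glu_5ht = NA_real_,             # calibrated
      glu_da = NA_real_,              # calibrated
      gv_da = NA_real_,               # calibrated
      ht5_gv = NA_real_,              # calibrated
      ht5_gd = if (sign[i] < 0) NA_real_ else fw[["ht5_gd_exc"]],
      gv_gd = NA_real_,               # calibrated (A/L)
      da_5ht = switch(arch_id, A = fw[["da_5ht_A"]],
                      B = fw[["da_5ht_BC"]], C = fw[["da_5ht_BC"]],
                      fw[["da_5ht_DEHL"]]),
      da_gd = if (arch_id == "A") fw[["da_gd_A"]] else fw[["da_gd_G"]],
      da_gv = fw[["da_gv"]],
      fw[[n]]
    )
  }
  w
}

#' D2 receptor-mediated connections of a variant
#'
#' The set of connections whose weights a simulated D2 agonist scales: every
#' connection in the variant whose source is the VTA DA population, always
#' including the DA autoreceptor self-inhibition.
#'
#' @param variant A `drnvta_variant`.
#' @return Data frame of the variant's D2-tagged edges.
#' @export
d2_connections <- function(variant) {
  e <- variant$edges
  e[e$d2, ]
}

#' @export
print.drnvta_variant <- function(x, ...) {
  cat(sprintf("<drnvta_variant #%d> architecture %s, Type %s 5-HT\n",
              x$index, x$architecture, x$serotonin_type))
  if (length(x$signs)) {
    cat("  sign choices:",
        paste(sprintf("%s%s", names(x$signs), ifelse(x$signs > 0, "+", "-")),
              collapse = ", "), "\n")
  }
  cat(sprintf("  %d edges; extra reward inhibition: %s\n",
              nrow(x$edges),
              format(x$extra_reward_inhibition)))
  invisible(x)
}
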