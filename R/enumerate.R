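# Reference enumeration of the reaction network for a given state, in plain
# R.  Intended for audits, small-network analysis (master-equation checks)
# and rate logging; the simulation engine builds the same network
# incrementally in compiled code.

sig_of <- function(tag, shape) sprintf("%s:%d,%d,%d", tag, shape[1], shape[2], shape[3])

product_sig <- function(shapes, tags) {
  paste(sort(mapply(function(s, t) sig_of(t, s), shapes, tags)), collapse = " + ")
}

tag_of_shape <- function(shape, parent_tag) {
  if (prod(shape) == 1) "MONOMER" else parent_tag
}

#' Enumerate the reaction set of a state
#'
#' Builds every geometrically allowed join, compound collision-with-split
#' and split among the species present, with rate constants and propensities,
#' after pruning.  Split channels are listed per cleavage position (so each
#' row has definite products); the propensity of the whole multiplicity
#' class is the per-position propensity summed over rows.  Monomer-monomer
#' collisions are listed once per contact axis and polymorph outcome, each
#' carrying an equal share of the collision propensity (equiprobable
#' commitment).
#'
#' @param state a [system_state()].
#' @param ap_spec,p_spec the two [polymorph_spec()]s.
#' @param polymorphs enabled polymorph labels.
#' @param cond a [solvent_conditions()].
#' @param prune_threshold channels with smaller rate constants are dropped.
#' @return data frame: `kind`, `axis`, `reactants`, `products`, `k`
#'   (m^3/s for bimolecular, 1/s for unimolecular), `propensity` (1/s),
#'   `n_cleavages`.
#' @export
enumerate_reactions <- function(state, ap_spec = default_ap_spec(),
                                p_spec = default_p_spec(),
                                polymorphs = c("AP", "P"),
                                cond = solvent_conditions(),
                                prune_threshold = 1e-50) {
  stopifnot(inherits(state, "system_state"))
  polymorphs <- match.arg(polymorphs, c("AP", "P"), several.ok = TRUE)
  sp <- state$species
  sp <- sp[sp$count > 0, , drop = FALSE]
  V <- state$volume
  specs <- list(AP = ap_spec, P = p_spec)
  tau0 <- lapply(specs, monomer_tau0, cond = cond)
  rows <- list()
  add <- function(kind, axis, reactants, products, k, propensity, n_cleav = 0L) {
    if (prune_rate(k, prune_threshold)) return(invisible())
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, axis = axis, reactants = reactants, products = products,
      k = k, propensity = propensity, n_cleavages = n_cleav)
  }
  shapes <- lapply(seq_len(nrow(sp)), function(i)
    c(sp$n_a[i], sp$n_b[i], sp$n_c[i]))

  # splits, one row per cleavage position
  for (i in seq_len(nrow(sp))) {
    tag <- sp$tag[i]
    if (tag == "MONOMER") next
    shp <- shapes[[i]]
    spec_i <- specs[[tag]]
    emit_split <- function(d, pos, plane_axis) {
      left <- shp; left[d] <- pos
      right <- shp; right[d] <- shp[d] - pos
      k <- split_rate_constant(as_shape(shp), split_plane(plane_axis),
                               spec_i, tau0[[tag]], cond)
      add("split", c("a", "b", "c")[d], sig_of(tag, shp),
          product_sig(list(left, right),
                      c(tag_of_shape(left, tag), tag_of_shape(right, tag))),
          k, k * sp$count[i])
    }
    if (shp[1] >= 2) for (m in 1:(shp[1] - 1)) emit_split(1, m, "a")
    if (shp[3] >= 2) for (m in 1:(shp[3] - 1)) emit_split(3, m, "c")
    if (shp[2] == 2) emit_split(2, 1, "zip")
    if (shp[2] >= 4) for (m in seq(2, shp[2] - 2, by = 2)) emit_split(2, m, "b")
  }

  # joins (simple and compound)
  for (i in seq_len(nrow(sp))) for (j in i:nrow(sp)) {
    ti <- sp$tag[i]; tj <- sp$tag[j]
    homo <- i == j
    if (ti == "MONOMER" && tj == "MONOMER") {
      n <- sp$count[i]
      for (ax in 1:3) {
        ks <- vapply(polymorphs, function(pm)
          resolve_join_channel(specs[[pm]], shapes[[i]], shapes[[j]], ax,
                               cond, tau0[[pm]])$k, numeric(1))
        kbar <- mean(ks)
        for (pm in polymorphs) {
          dimer <- c(1, 1, 1); dimer[ax] <- 2
          add("join", c("a", "b", "c")[ax],
              paste(sig_of("MONOMER", c(1, 1, 1)), "+",
                    sig_of("MONOMER", c(1, 1, 1))),
              sig_of(pm, dimer), kbar,
              kbar * n * (n - 1) / (2 * V) / length(polymorphs))
        }
      }
      next
    }
    tag <- if (ti == "MONOMER") tj else ti
    if (tj != "MONOMER" && ti != "MONOMER" && ti != tj) next
    if (!(tag %in% polymorphs)) next
    spec_t <- specs[[tag]]
    for (ax in 1:3) {
      ch <- resolve_join_channel(spec_t, shapes[[i]], shapes[[j]], ax,
                                 cond, tau0[[tag]])
      if (is.null(ch)) next
      prop <- bimolecular_propensity(ch$k, sp$count[i], sp$count[j], V, homo)
      add(ch$kind, c("a", "b", "c")[ax],
          paste(sig_of(ti, shapes[[i]]), "+", sig_of(tj, shapes[[j]])),
          product_sig(ch$products,
                      vapply(ch$products, tag_of_shape, character(1), tag)),
          ch$k, prop, ch$n_cleavages)
    }
  }

  if (length(rows) == 0)
    return(data.frame(kind = character(), axis = character(),
                      reactants = character(), products = character(),
                      k = numeric(), propensity = numeric(),
                      n_cleavages = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
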