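# Equivalent fluidic circuit of the spore-loading design. Hydraulic
# resistances compose like electrical ones; the loading inlet imposes a
# volumetric inflow, the two outlets sit at a common reference pressure.
# The serpentine bypass between loading chamber and Outlet 1 is dimensioned
# so that most of the spore-laden flow passes through the growth channels
# (toward Outlet 2) at the start of loading, while still providing an
# escape path once channels become blocked by trapped spores.

#' Fluidic resistor network
#'
#' @param resistors Data frame with columns `from`, `to` (node names) and
#'   `resistance` (uN s um^-5, > 0); optionally `label`.
#' @param sources Data frame with columns `node` and `inflow` (um^3/s;
#'   negative = withdrawal).
#' @param reference Name of the reference-pressure node (pressure 0).
#' @return An object of class `fluidic_network`.
#' @export
fluidic_network <- function(resistors, sources, reference) {
  req <- c("from", "to", "resistance")
  if (!is.data.frame(resistors) || !all(req %in% names(resistors)))
    stop("`resistors` needs columns from, to, resistance")
  if (is.null(resistors$label))
    resistors$label <- paste(resistors$from, resistors$to, sep = "-")
  if (any(!is.finite(resistors$resistance)) || any(resistors$resistance <= 0))
    stop("all resistances must be positive and finite")
  if (!is.data.frame(sources) || !all(c("node", "inflow") %in% names(sources)))
    stop("`sources` needs columns node, inflow")
  nodes <- unique(c(resistors$from, resistors$to, sources$node, reference))
  if (!reference %in% nodes) stop("reference node not in network")
  structure(list(nodes = nodes, resistors = resistors, sources = sources,
                 reference = reference),
            class = "fluidic_network")
}

# connected components by breadth-first walk over resistor edges
network_components <- function(net) {
  comp <- stats::setNames(rep(NA_integer_, length(net$nodes)), net$nodes)
  k <- 0L
  for (start in net$nodes) {
    if (!is.na(comp[start])) next
    k <- k + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      nb <- c(net$resistors$to[net$resistors$from == v],
              net$resistors$from[net$resistors$to == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

#' Solve a fluidic network by nodal analysis
#'
#' Builds the conductance Laplacian, grounds the reference node and solves
#' for node pressures; branch flows follow from the linear resistor law.
#' Conservation of flow is verified at every node to a relative residual
#' below 1e-10.
#'
#' @param network A [fluidic_network()].
#' @return List with `pressures` (named, uN um^-2 = MPa, reference = 0),
#'   `flows` (the resistor table plus a `flow` column, um^3/s, positive
#'   from `from` to `to`) and the conservation `residual`.
#' @export
solve_network <- function(network) {
  if (!inherits(network, "fluidic_network"))
    stop("`network` must be a fluidic_network")
  comp <- network_components(network)
  ref_comp <- comp[network$reference]
  floating <- names(comp)[comp != ref_comp]
  if (length(floating))
    stop("singular system: node(s) not connected to the reference: ",
         paste(floating, collapse = ", "))
  nodes <- network$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  G <- matrix(0, n, n)
  for (i in seq_len(nrow(network$resistors))) {
    a <- idx[network$resistors$from[i]]
    b <- idx[network$resistors$to[i]]
    g <- 1 / network$resistors$resistance[i]
    G[a, a] <- G[a, a] + g; G[b, b] <- G[b, b] + g
    G[a, b] <- G[a, b] - g; G[b, a] <- G[b, a] - g
  }
  q <- numeric(n)
  for (i in seq_len(nrow(network$sources)))
    q[idx[network$sources$node[i]]] <-
      q[idx[network$sources$node[i]]] + network$sources$inflow[i]
  r <- idx[network$reference]
  p <- numeric(n)
  p[-r] <- solve(G[-r, -r, drop = FALSE], q[-r])
  flows <- network$resistors
  flows$flow <- (p[idx[flows$from]] - p[idx[flows$to]]) / flows$resistance
  resid <- G %*% p - q
  resid[r] <- 0 # reference node absorbs the balance
  scale <- max(abs(q), max(abs(flows$flow)), 1e-300)
  list(pressures = stats::setNames(p, nodes), flows = flows,
       residual = max(abs(resid)) / scale)
}

#' Spore-loading design parameters
#'
#' The loading half of the chip: N identical growth channels in parallel
#' connect the loading chamber to the measurement side, and a serpentine
#' bypass connects it to the loading outlet. By the design rule the
#' serpentine resistance is `ratio_target` times the parallel resistance of
#' all open growth channels, which makes the growth-channel/serpentine flow
#' ratio equal `ratio_target` at the start of loading.
#'
#' @param n_channels Number of growth channels (default 80).
#' @param hydraulic_diameter Growth-channel hydraulic diameter in um
#'   (default 2.8); the channel is modelled as a square duct of this side.
#' @param channel_length Growth-channel length in um (default 100; the
#'   printed design does not state it, and only resistance ratios matter
#'   for the flow partition).
#' @param ratio_target Design flow ratio (default 20).
#' @param serpentine_resistance Serpentine resistance in uN s um^-5;
#'   `NULL` (default) derives it from the ratio rule, `Inf` removes the
#'   serpentine branch.
#' @param chamber_resistance,outlet_resistance Downstream resistances
#'   between the growth channels and Outlet 2 (default 0: ideal outlets).
#' @param blocked Number of growth channels blocked by trapped spores
#'   (0..N); blocked channels are treated as perfect plugs and removed.
#' @param loading_flow_ul_min Imposed loading inflow in uL/min (default
#'   108).
#' @return An object of class `loading_design`.
#' @export
loading_design <- function(n_channels = 80, hydraulic_diameter = 2.8,
                           channel_length = 100, ratio_target = 20,
                           serpentine_resistance = NULL,
                           chamber_resistance = 0, outlet_resistance = 0,
                           blocked = 0, loading_flow_ul_min = 108) {
  if (n_channels < 1) stop("`n_channels` must be >= 1")
  if (blocked < 0 || blocked > n_channels)
    stop("`blocked` must lie in 0..n_channels")
  if (hydraulic_diameter <= 0 || channel_length <= 0)
    stop("growth-channel dimensions must be positive")
  if (chamber_resistance < 0 || outlet_resistance < 0)
    stop("downstream resistances must be >= 0")
  structure(
    list(n_channels = as.integer(n_channels),
         hydraulic_diameter = hydraulic_diameter,
         channel_length = channel_length,
         ratio_target = ratio_target,
         serpentine_resistance = serpentine_resistance,
         chamber_resistance = chamber_resistance,
         outlet_resistance = outlet_resistance,
         blocked = as.integer(blocked),
         loading_flow_ul_min = loading_flow_ul_min),
    class = "loading_design"
  )
}

# resistance of one growth channel (square duct of side d_h)
growth_channel_resistance <- function(design, fluid) {
  g <- channel_geometry(design$hydraulic_diameter, design$hydraulic_diameter,
                        "floor")
  resistance_per_length(g, fluid) * design$channel_length
}

#' Build the equivalent circuit of the loading design
#'
#' Nodes: `inlet` (= loading chamber, where the inflow is imposed),
#' `measurement` (downstream of the growth channels, present only when the
#' downstream resistance is non-zero) and the common reference `outlet`.
#' Branches: the serpentine (labelled `"serpentine"`) and the parallel
#' combination of the open growth channels (labelled `"growth"`).
#'
#' @param design A [loading_design()].
#' @param fluid A [fluid()].
#' @return A [fluidic_network()]; attribute `"resistances"` carries the
#'   single-channel, parallel-growth and serpentine resistances.
#' @export
build_network <- function(design, fluid) {
  if (!inherits(design, "loading_design"))
    stop("`design` must be a loading_design")
  r_single <- growth_channel_resistance(design, fluid)
  n_open <- design$n_channels - design$blocked
  r_serp <- design$serpentine_resistance
  if (is.null(r_serp))
    r_serp <- design$ratio_target * r_single / design$n_channels
  has_serp <- is.finite(r_serp)
  if (n_open == 0 && !has_serp)
    stop("disconnected graph: all growth channels blocked and no serpentine")
  res <- list()
  if (has_serp)
    res$serp <- data.frame(from = "inlet", to = "outlet",
                           resistance = r_serp, label = "serpentine")
  if (n_open > 0) {
    r_down <- design$chamber_resistance + design$outlet_resistance
    if (r_down > 0) {
      res$growth <- data.frame(from = "inlet", to = "measurement",
                               resistance = r_single / n_open,
                               label = "growth")
      res$down <- data.frame(from = "measurement", to = "outlet",
                             resistance = r_down, label = "downstream")
    } else {
      res$growth <- data.frame(from = "inlet", to = "outlet",
                               resistance = r_single / n_open,
                               label = "growth")
    }
  }
  net <- fluidic_network(
    do.call(rbind, res),
    sources = data.frame(node = "inlet",
                         inflow = ul_min_to_um3_s(design$loading_flow_ul_min)),
    reference = "outlet"
  )
  attr(net, "resistances") <- list(single = r_single,
                                   parallel = if (n_open > 0) r_single / n_open
                                              else Inf,
                                   serpentine = if (has_serp) r_serp else Inf)
  net
}

#' Flow partition and chamber pressure of the loading design
#'
#' @param design A [loading_design()].
#' @param fluid A [fluid()].
#' @return List with `ratio` (growth-channel flow / serpentine flow),
#'   `chamber_pressure_Pa` (loading-chamber pressure relative to the
#'   outlets) and the full `solution` of [solve_network()].
#' @export
loading_flow_ratio <- function(design, fluid) {
  net <- build_network(design, fluid)
  sol <- solve_network(net)
  q_growth <- sum(sol$flows$flow[sol$flows$label == "growth"])
  q_serp <- sum(sol$flows$flow[sol$flows$label == "serpentine"])
  ratio <- if (q_serp == 0) Inf else q_growth / q_serp
  list(ratio = ratio,
       chamber_pressure_Pa = unname(sol$pressures["inlet"]) * 1e6,
       solution = sol)
}

#' Sweep the number of spore-blocked growth channels
#'
#' Re-solves the circuit for each blocking count. As channels fill with
#' spores the flow ratio toward the measurement side decreases while the
#' chamber pressure rises, up to the all-blocked maximum set by the
#' serpentine path alone.
#'
#' @param design A [loading_design()].
#' @param fluid A [fluid()].
#' @param blocked Integer vector of blocking counts (default `0:N`).
#' @return Data frame with columns `blocked`, `ratio`, `pressure_Pa`.
#' @export
blocking_sweep <- function(design, fluid, blocked = 0:design$n_channels) {
  rows <- lapply(blocked, function(b) {
    d <- design; d$blocked <- as.integer(b)
    lf <- loading_flow_ratio(d, fluid)
    data.frame(blocked = b, ratio = lf$ratio,
               pressure_Pa = lf$chamber_pressure_Pa)
  })
  do.call(rbind, rows)
}
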