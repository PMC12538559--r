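#' Parameters of the synthetic stack generator
#'
#' Defines the study conditions emulated by the kinetic Monte Carlo
#' generator: stacks of `n_dimers` quadruple-H-bonded dimers with core-core
#' dimer separation `d_dimer` (0.6 nm) and stacking spacing `d_stack`
#' (0.37 nm), Poissonian dimer rupture with a tip rate far exceeding the
#' backbone rate, sliding of unbound monomers along the stack axis,
#' rebinding (self-healing) of co-located complementary unbound monomers,
#' and thermal positional jitter.
#'
#' @param n_dimers Number of dimers in the stack.
#' @param d_dimer Core-core separation of a bound dimer (nm).
#' @param d_stack Stacking spacing along the axis (nm).
#' @param k_tip Rupture rate of intact dimers sitting at the lattice end
#'   sites (1/ps).
#' @param k_back Rupture rate of interior (backbone) dimers (1/ps); must not
#'   exceed `k_tip`.
#' @param k_slide Hop rate of a travelling monomer along the axis (1/ps);
#'   a hop beyond the lattice ends releases the monomer into solution.
#' @param k_rebind Binding rate of a travelling monomer co-located with a
#'   complementary (opposite side) stacked-unbound monomer (1/ps).
#' @param noise_sigma Thermal positional jitter, per coordinate (nm).
#' @param unbound_wobble Extra rigid-body positional wobble of
#'   stacked-unbound monomers (nm, per frame): a monomer that has lost its
#'   dimerization H-bonds is only loosely attached and rattles against the
#'   stack, making its neighbourhood the most dynamic one. Decorative
#'   (rendering only): does not affect the ground truth.
#' @param dt_frame Frame interval (ps).
#' @param n_frames Number of frames.
#' @param box Cubic box edge (nm).
#' @param seed Integer seed; the event stream and the decorative noise
#'   stream are derived from it deterministically.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_dimers = 20L, d_dimer = 0.6, d_stack = 0.37,
                             k_tip = 5e-5, k_back = 5e-12, k_slide = 2e-3,
                             k_rebind = 1e-3, noise_sigma = 0.015,
                             unbound_wobble = 0.05,
                             dt_frame = 100, n_frames = 400L, box = 12,
                             seed = 1L) {
  stopifnot(n_dimers >= 1, d_dimer > d_stack, d_stack > 0,
            k_tip >= 0, k_back >= 0, k_tip >= k_back,
            k_slide >= 0, k_rebind >= 0, noise_sigma >= 0,
            unbound_wobble >= 0, dt_frame > 0, n_frames >= 1, box > 0)
  structure(list(n_dimers = as.integer(n_dimers), d_dimer = d_dimer,
                 d_stack = d_stack, k_tip = k_tip, k_back = k_back,
                 k_slide = k_slide, k_rebind = k_rebind,
                 noise_sigma = noise_sigma,
                 unbound_wobble = unbound_wobble, dt_frame = dt_frame,
                 n_frames = as.integer(n_frames), box = box,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

# Rigid 5-point monomer motif in local coordinates (one side of a dimer).
# The DDAA hydrogen-bond row sits at x = -d_dimer/6 so that paired hb atoms
# are d_dimer/3 apart (0.2 nm at defaults, inside D0 of the default
# switching function); the core-center atom sits at -d_dimer/2 so the
# core-core separation of a bound pair is exactly d_dimer. `sgn` = -1 for
# the A side, +1 for B; `lateral` shifts the motif outward (unbound state).
.motif <- function(sgn, site, d_dimer, d_stack, origin, lateral = 0) {
  hb_x <- sgn * (d_dimer / 6 + lateral)
  core_x <- sgn * (d_dimer / 2 + lateral)
  z <- (site - 1) * d_stack
  xyz <- rbind(
    cbind(hb_x, c(-0.225, -0.075, 0.075, 0.225), z),
    cbind(core_x, 0, z))
  sweep(xyz, 2, origin, `+`)
}

#' Build a pre-stacked synthetic supramolecular polymer
#'
#' Constructs a stack of `n_dimers` dimers: each monomer is a rigid 5-point
#' motif (4 hydrogen-bond atoms in a planar DDAA row plus one core-center
#' atom), partners face each other across the dimer gap, and consecutive
#' dimers stack along z at `d_stack`.
#'
#' @param params A [synthetic_params()].
#' @param stack_id Stack identifier.
#' @param origin Cartesian origin of lattice site 1 (defaults to centering
#'   the stack in the box).
#' @param id_offset,atom_offset Numbering offsets, used by [make_bundle()].
#' @return List with `topology` (a [stack_topology()] whose monomer records
#'   additionally carry the generator fields `site`, `parity` and
#'   `center_atom`), `coords0` (atoms x 3), and `box`.
#' @export
build_stack <- function(params = synthetic_params(), stack_id = "S1",
                        origin = NULL, id_offset = 0L, atom_offset = 0L) {
  p <- params
  if (p$d_dimer / 3 > switching_params()$D0) {
    warning("hb pair distance ", signif(p$d_dimer / 3, 3),
            " nm exceeds the default switching D0; frame-0 counts will be < 4")
  }
  if (is.null(origin)) {
    span <- (p$n_dimers - 1) * p$d_stack
    origin <- c(p$box / 2, p$box / 2, (p$box - span) / 2)
  }
  monomers <- list()
  coords <- matrix(NA_real_, p$n_dimers * 10L, 3L)
  dimers0 <- vector("list", p$n_dimers)
  for (k in seq_len(p$n_dimers)) {
    for (s in 1:2) {                       # 1 = A side, 2 = B side
      sgn <- c(-1, 1)[s]
      mi <- (k - 1L) * 2L + s
      at <- atom_offset + (mi - 1L) * 5L + 1:5
      coords[(mi - 1L) * 5L + 1:5, ] <- .motif(sgn, k, p$d_dimer, p$d_stack, origin)
      monomers[[mi]] <- list(
        id = paste0("M", id_offset + mi), stack = stack_id,
        atoms = at, hb = at[1:4], core = at,
        site = k, parity = c("A", "B")[s], center_atom = at[5])
    }
    dimers0[[k]] <- c(paste0("M", id_offset + (k - 1L) * 2L + 1L),
                      paste0("M", id_offset + (k - 1L) * 2L + 2L))
  }
  topo <- stack_topology(monomers, dimers0,
                         axis_order = setNames(list(seq_len(p$n_dimers)), stack_id),
                         n_atoms = atom_offset + p$n_dimers * 10L)
  list(topology = topo, coords0 = coords, box = rep(p$box, 3))
}

#' Build a bundle of parallel stacks
#'
#' Places `n_stacks` copies of the [build_stack()] lattice side by side at a
#' given lateral spacing (along x), with distinct stack ids.
#'
#' @param n_stacks Number of stacks (>= 2).
#' @param params A [synthetic_params()].
#' @param spacing Lateral axis-to-axis distance (nm), > 0.
#' @return As [build_stack()]: `topology`, `coords0`, `box`.
#' @export
make_bundle <- function(n_stacks, params = synthetic_params(), spacing = 2) {
  stopifnot(n_stacks >= 2)
  if (spacing <= 0) stop("spacing must be > 0")
  p <- params
  span <- (p$n_dimers - 1) * p$d_stack
  width <- (n_stacks - 1) * spacing
  parts <- lapply(seq_len(n_stacks), function(i) {
    build_stack(p, stack_id = paste0("S", i),
                origin = c((p$box - width) / 2 + (i - 1) * spacing,
                           p$box / 2, (p$box - span) / 2),
                id_offset = (i - 1L) * 2L * p$n_dimers,
                atom_offset = (i - 1L) * 10L * p$n_dimers)
  })
  monomers <- do.call(c, lapply(parts, function(x) unname(x$topology$monomers)))
  dimers0 <- do.call(c, lapply(parts, function(x) x$topology$dimers0))
  axis_order <- list()
  off <- 0L
  for (i in seq_len(n_stacks)) {
    axis_order[[paste0("S", i)]] <- off + seq_len(p$n_dimers)
    off <- off + p$n_dimers
  }
  topo <- stack_topology(monomers, dimers0, axis_order = axis_order,
                         n_atoms = n_stacks * 10L * p$n_dimers)
  attr(topo, "bundle_spacing") <- spacing
  coords <- do.call(rbind, lapply(parts, `[[`, "coords0"))
  list(topology = topo, coords0 = coords, box = rep(p$box, 3))
}

#' Kinetic Monte Carlo simulation of monomer exchange
#'
#' Direct (Gillespie) stochastic simulation over three event channels
#' mirroring the defect/self-healing pathway: *rupture* of an intact dimer
#' (rate `k_tip` at the lattice end sites, `k_back` elsewhere) leaves one
#' partner stacked-unbound -- it keeps its lattice position, loosely
#' attached and rattling -- while the other starts travelling, sliding
#' along the polymer surface; *slide* steps (rate `k_slide`) move a
#' travelling monomer by one lattice site, a hop beyond the ends releasing
#' it into solution; *rebind* (rate `k_rebind`) joins a travelling monomer
#' that reaches the site of a complementary stacked-unbound monomer into a
#' full dimer again -- self-healing, possibly with a different partner than
#' at t = 0. Frames are sampled every `dt_frame` with Gaussian jitter.
#'
#' The event stream and the decorative rendering noise use two RNG
#' substreams derived from `params$seed`, so the ground truth is invariant
#' under changes of `noise_sigma` and identical seeds give bit-identical
#' output.
#'
#' @param topo Topology from [build_stack()] or [make_bundle()].
#' @param coords0 Frame-0 coordinates (unused directly; retained for
#'   interface symmetry and validated against the topology).
#' @param params The [synthetic_params()] used to build the system.
#' @return List with `trajectory` (a [stack_trajectory()]) and `truth`
#'   (class `ground_truth`): per-frame per-monomer state labels (`bound`,
#'   `stacked-unbound`, `travelling`), the event table, per-frame lattice
#'   sites, and the planted per-class rates.
#' @export
simulate_exchange <- function(topo, coords0, params) {
  p <- params
  nm <- n_monomers(topo)
  ids <- monomer_ids(topo)
  if (!is.null(coords0) && nrow(coords0) != topo$n_atoms) {
    stop("coords0 atom count does not match topology")
  }
  site <- vapply(topo$monomers, function(m) as.integer(m$site), integer(1))
  parity <- vapply(topo$monomers, function(m) m$parity, character(1))
  stack <- vapply(topo$monomers, function(m) m$stack, character(1))
  D_of <- vapply(topo$axis_order, length, integer(1))   # dimers per stack
  tipsite <- function(s, st) s == 1L | s == unname(D_of[st])

  state <- rep("bound", nm)
  partner <- rep(NA_integer_, nm)
  for (d in topo$dimers0) {
    i <- match(d[1], ids); j <- match(d[2], ids)
    partner[i] <- j; partner[j] <- i
  }

  nf <- p$n_frames
  frame_times <- (seq_len(nf) - 1) * p$dt_frame
  states_mat <- matrix(NA_character_, nm, nf, dimnames = list(ids, NULL))
  internal_mat <- matrix(NA_character_, nm, nf, dimnames = list(ids, NULL))
  sites_mat <- matrix(NA_integer_, nm, nf, dimnames = list(ids, NULL))
  ev_time <- numeric(0); ev_type <- character(0)
  ev_m1 <- character(0); ev_m2 <- character(0); ev_site <- integer(0)

  # internal states: bound / waiting (stacked-unbound stayer) /
  # sliding (travelling, on-lattice) / dissolved (travelling, off-lattice)
  run_kmc <- function() {
    t_now <- 0
    f <- 1L
    warned_static <- FALSE
    public <- c(bound = "bound", waiting = "stacked-unbound",
                sliding = "travelling", dissolved = "travelling")
    snapshot_upto <- function(t_next) {
      while (f <= nf && frame_times[f] <= t_next) {
        states_mat[, f] <<- unname(public[state])
        sites_mat[, f] <<- site
        internal_mat[, f] <<- state
        f <<- f + 1L
      }
    }
    repeat {
      # --- assemble event channels
      bound_i <- which(state == "bound" & seq_len(nm) < partner)
      r_rup <- if (length(bound_i)) {
        ifelse(tipsite(site[bound_i], stack[bound_i]), p$k_tip, p$k_back)
      } else numeric(0)
      sld <- which(state == "sliding")
      r_slide <- rep(p$k_slide, length(sld))
      reb_a <- integer(0); reb_b <- integer(0)
      if (p$k_rebind > 0 && length(sld)) {
        wtg <- which(state == "waiting")
        for (i in sld) {
          js <- wtg[parity[wtg] != parity[i] & site[wtg] == site[i] &
                    stack[wtg] == stack[i]]
          if (length(js)) { reb_a <- c(reb_a, rep(i, length(js))); reb_b <- c(reb_b, js) }
        }
      }
      r_reb <- rep(p$k_rebind, length(reb_a))
      rates <- c(r_rup, r_slide, r_reb)
      total <- sum(rates)
      if (total == 0) {
        if (!warned_static && f <= nf && t_now == 0) {
          warning("zero total event rate: trajectory is static")
          warned_static <- TRUE
        }
        snapshot_upto(Inf)
        break
      }
      t_next <- t_now + stats::rexp(1, total)
      snapshot_upto(t_next)
      if (f > nf && t_next > frame_times[nf]) break
      t_now <- t_next
      pick <- sample.int(length(rates), 1L, prob = rates)
      if (pick <= length(bound_i)) {
        i <- bound_i[pick]; j <- partner[i]
        stay_first <- sample(c(TRUE, FALSE), 1L)
        stayer <- if (stay_first) i else j
        leaver <- if (stay_first) j else i
        state[stayer] <<- "waiting"
        state[leaver] <<- "sliding"
        partner[c(i, j)] <<- NA_integer_
        ev_time <<- c(ev_time, t_now); ev_type <<- c(ev_type, "rupture")
        ev_m1 <<- c(ev_m1, ids[stayer]); ev_m2 <<- c(ev_m2, ids[leaver])
        ev_site <<- c(ev_site, site[i])
      } else if (pick <= length(bound_i) + length(sld)) {
        i <- sld[pick - length(bound_i)]
        dir <- sample(c(-1L, 1L), 1L)
        ns <- site[i] + dir
        if (ns < 1L || ns > D_of[[stack[i]]]) {
          state[i] <<- "dissolved"; site[i] <<- NA_integer_
          ev_site <<- c(ev_site, NA_integer_)
        } else {
          site[i] <<- ns
          ev_site <<- c(ev_site, ns)
        }
        ev_time <<- c(ev_time, t_now); ev_type <<- c(ev_type, "slide-step")
        ev_m1 <<- c(ev_m1, ids[i]); ev_m2 <<- c(ev_m2, NA_character_)
      } else {
        k <- pick - length(bound_i) - length(sld)
        i <- reb_a[k]; j <- reb_b[k]
        state[c(i, j)] <<- "bound"
        partner[i] <<- j; partner[j] <<- i
        ev_time <<- c(ev_time, t_now); ev_type <<- c(ev_type, "rebind")
        ev_m1 <<- c(ev_m1, ids[i]); ev_m2 <<- c(ev_m2, ids[j])
        ev_site <<- c(ev_site, site[i])
      }
    }
  }
  with_seed(p$seed, run_kmc())

  events <- data.frame(time = ev_time, type = ev_type, monomer = ev_m1,
                       partner = ev_m2, site = ev_site,
                       stringsAsFactors = FALSE)
  truth <- structure(
    list(states = states_mat, internal = internal_mat, sites = sites_mat,
         events = events,
         rates = list(tip = p$k_tip, backbone = p$k_back,
                      slide = p$k_slide, rebind = p$k_rebind),
         params = p),
    class = "ground_truth")

  traj <- with_seed(p$seed + 1000003L,
                    render_frames(topo, truth, frame_times, p))
  list(trajectory = traj, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$states), "monomers x", ncol(x$states),
      "frames;", nrow(x$events), "events (",
      sum(x$events$type == "rupture"), "ruptures,",
      sum(x$events$type == "rebind"), "rebinds )\n")
  invisible(x)
}

# Render coordinate frames from the KMC state timeline. Bound monomers sit
# on the lattice, stacked-unbound ones are shifted 0.45 nm outward and track
# their current site, travelling monomers get a dispersed far anchor plus a
# slow random walk; Gaussian jitter noise_sigma is added to every atom.
render_frames <- function(topo, truth, frame_times, p) {
  nm <- n_monomers(topo)
  ids <- monomer_ids(topo)
  nf <- length(frame_times)
  nat <- topo$n_atoms
  span <- (max(vapply(topo$axis_order, length, integer(1))) - 1) * p$d_stack
  coords <- array(NA_real_, c(nat, 3, nf))
  trav_pos <- matrix(NA_real_, nm, 3)
  trav_count <- 0L
  golden <- pi * (3 - sqrt(5))
  for (f in seq_len(nf)) {
    for (mi in seq_len(nm)) {
      m <- topo$monomers[[mi]]
      st <- truth$internal[mi, f]
      sgn <- if (m$parity == "A") -1 else 1
      org <- origin_from_topology(topo, m$stack, p)
      if (st == "bound") {
        xyz <- .motif(sgn, truth$sites[mi, f], p$d_dimer, p$d_stack, org)
        trav_pos[mi, ] <- NA_real_
      } else if (st == "waiting") {
        # stacked-unbound: stays at its site, shifted 0.45 nm off the
        # stack (loosely attached) and rattling there
        xyz <- .motif(sgn, truth$sites[mi, f], p$d_dimer, p$d_stack, org,
                      lateral = 0.45)
        if (p$unbound_wobble > 0) {
          xyz <- sweep(xyz, 2, stats::rnorm(3, 0, p$unbound_wobble), `+`)
        }
        trav_pos[mi, ] <- NA_real_
      } else if (st == "sliding") {
        # travelling along the polymer surface: groove 0.75 nm off the
        # H-bond plane (A above, B below), outside the descriptor shell
        xyz <- .motif(sgn, truth$sites[mi, f], p$d_dimer, p$d_stack, org)
        xyz <- sweep(xyz, 2, c(-sgn * p$d_dimer / 6, -sgn * 0.75, 0), `+`)
        trav_pos[mi, ] <- NA_real_
      } else { # dissolved in solution
        if (anyNA(trav_pos[mi, ])) {
          trav_count <- trav_count + 1L
          ang <- golden * trav_count
          trav_pos[mi, ] <- org + c(3 * cos(ang), 3 * sin(ang),
                                    span * ((trav_count * 0.381966) %% 1))
        } else {
          trav_pos[mi, ] <- trav_pos[mi, ] + stats::rnorm(3, 0, 0.05)
        }
        xyz <- .motif(sgn, 1L, p$d_dimer, p$d_stack, trav_pos[mi, ])
      }
      coords[m$atoms, , f] <- xyz
    }
    if (p$noise_sigma > 0) {
      coords[, , f] <- coords[, , f] + stats::rnorm(nat * 3, 0, p$noise_sigma)
    }
  }
  stack_trajectory(coords, frame_times, rep(p$box, 3))
}

# Origin of a stack's lattice (position of site 1's dimer midpoint), derived
# from the generator's layout convention stored in the monomer records.
origin_from_topology <- function(topo, stack_id, p) {
  span <- (length(topo$axis_order[[stack_id]]) - 1) * p$d_stack
  # A-side core atom of site 1 sits at origin + (-d_dimer/2, 0, 0); we do
  # not keep explicit origins, so reconstruct from the build/make layout
  n_st <- length(topo$axis_order)
  idx <- match(stack_id, names(topo$axis_order))
  if (n_st == 1L) return(c(p$box / 2, p$box / 2, (p$box - span) / 2))
  spacing <- attr(topo, "bundle_spacing")
  if (is.null(spacing)) spacing <- 2
  width <- (n_st - 1) * spacing
  c((p$box - width) / 2 + (idx - 1) * spacing, p$box / 2, (p$box - span) / 2)
}

#' Sample biased transition-time traces with known unbiased rates
#'
#' For each run draws an unbiased transition time from Exp(`true_tau`) and
#' constructs a well-tempered-style monotone bias staircase V(t) whose
#' deposition heights shrink as h0 * exp(-V/((gamma-1) kB T)). The biased
#' stopping time t_b is defined so that the running acceleration integral
#' of exp(beta V) over [0, t_b] equals the drawn unbiased time; by
#' construction [unbiased_time()] applied to the returned trace recovers
#' the draw to machine precision.
#'
#' @param true_tau Planted unbiased characteristic time (ps), > 0.
#' @param bias_rate Initial Gaussian deposition height h0 (kJ/mol per
#'   deposition); 0 gives an unbiased trace whose stopping time equals the
#'   unbiased draw.
#' @param pace Deposition interval (ps).
#' @param n_runs Number of independent runs.
#' @param seed Integer seed.
#' @param temperature Temperature (K).
#' @param bias_factor Well-tempered bias factor gamma.
#' @return List with `traces` (list of [bias_trace()]), `transition_times`
#'   (biased stopping times, ps), and `unbiased_draws` (the planted times).
#' @export
sample_biased_transitions <- function(true_tau, bias_rate = 1.5, pace = 10,
                                      n_runs = 30L, seed = 1L,
                                      temperature = 298, bias_factor = 10) {
  stopifnot(true_tau > 0, pace > 0, n_runs >= 1, bias_rate >= 0)
  beta <- beta_from_temperature(temperature)
  kT <- 1 / beta
  with_seed(seed, {
    draws <- stats::rexp(n_runs, 1 / true_tau)
    traces <- vector("list", n_runs)
    t_b <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      t_u <- draws[r]
      times <- 0; Vs <- 0
      V <- 0; acc <- 0; t0 <- 0
      repeat {
        a_int <- pace * exp(beta * V)    # acceleration over this interval
        if (acc + a_int >= t_u) {
          dt_in <- (t_u - acc) / exp(beta * V)
          t_b[r] <- t0 + dt_in
          times <- c(times, t_b[r]); Vs <- c(Vs, V)
          break
        }
        acc <- acc + a_int
        t0 <- t0 + pace
        V <- V + bias_rate * exp(-V / ((bias_factor - 1) * kT))
        times <- c(times, t0); Vs <- c(Vs, V)
      }
      traces[[r]] <- bias_trace(times, Vs, temperature = temperature)
      attr(traces[[r]], "transition_time") <- t_b[r]
    }
    list(traces = traces, transition_times = t_b, unbiased_draws = draws)
  })
}

#' Write a synthetic dataset to disk
#'
#' Persists topology annotation (JSON), frame-0 coordinates and trajectory
#' (XYZ), ground truth (JSON + CSV state table) and a parameter manifest.
#'
#' @param sim Output of [simulate_exchange()].
#' @param topo The topology.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, topo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_topology_json(topo, file.path(dir, "topology.json"))
  write_trajectory_xyz(sim$trajectory, file.path(dir, "trajectory.xyz"))
  utils::write.csv(
    data.frame(monomer = rep(rownames(sim$truth$states), ncol(sim$truth$states)),
               frame = rep(seq_len(ncol(sim$truth$states)), each = nrow(sim$truth$states)),
               state = as.vector(sim$truth$states)),
    file.path(dir, "ground_truth_states.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$events, file.path(dir, "ground_truth_events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(rates = sim$truth$rates, params = unclass(sim$truth$params)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
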