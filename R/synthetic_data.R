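# Synthetic data: toy antibody-like complexes with planted contacts and
# binding modes, pose-score tables, and noisy sensorgrams with known kinetic
# truth. Every generator is a pure function of its spec (seed included).

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a toy antibody-ssDNA complex
#'
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @param n_nucleotides Ligand length (>= number of planted sites).
#' @param planted_mode Intended binding mode: `"FAB"`, `"MODE1"`, `"MODE2"` or
#'   `"MODE3"`.
#' @param planted_contact_sites Optional data frame (`chain`, `resnum`) of
#'   receptor sites each of which exactly one nucleotide will contact. When
#'   omitted, sites consistent with `planted_mode` under the default region
#'   map are drawn at random.
#' @param contact_distance Heavy-atom distance in Angstrom at which planted
#'   contacts sit (default 3, inside the default 4.5 cutoff).
#' @param spacing Receptor lattice spacing in Angstrom (default 10, so
#'   non-planted pairs stay well beyond any admissible cutoff).
#' @return List of class `complex_spec`.
#' @export
complex_spec <- function(seed = 1, n_nucleotides = 10,
                         planted_mode = "MODE1",
                         planted_contact_sites = NULL,
                         contact_distance = 3, spacing = 10) {
  stopifnot(planted_mode %in% c("FAB", "MODE1", "MODE2", "MODE3"),
            n_nucleotides >= 1, contact_distance > 0, spacing > contact_distance + 6)
  structure(list(seed = as.integer(seed), n_nucleotides = as.integer(n_nucleotides),
                 planted_mode = planted_mode,
                 planted_contact_sites = planted_contact_sites,
                 contact_distance = contact_distance, spacing = spacing),
            class = "complex_spec")
}

# receptor skeleton: CA-only residues on a 10 A lattice, one row per chain,
# covering every region of the default 1IGT-style map, plus one glycan chain.
toy_receptor_skeleton <- function(spacing) {
  mk <- function(chain, resnums, resnames, kind, atom, element, row) {
    data.frame(chain = chain, resnum = resnums, resname = resnames,
               atom = atom, element = element,
               x = seq_along(resnums) * spacing, y = row * spacing, z = 0,
               kind = kind, region = NA_character_, stringsAsFactors = FALSE)
  }
  aa_cycle <- function(n) rep(c("PRO", "GLU", "LYS", "ILE", "GLY", "SER"), length.out = n)
  heavy <- function(chain, row) {
    resnums <- c(10, 60, 110,          # VH
                 130, 180, 230,       # CH1
                 250, 300, 350,       # CH2
                 370, 423, 450,       # CH3 (423 mirrors the Glu423 hot spot)
                 458, 464, 470)       # hinge
    resnames <- aa_cycle(length(resnums))
    resnames[resnums == 423] <- "GLU"
    mk(chain, resnums, resnames, "amino_acid", "CA", "C", row)
  }
  light <- function(chain, row) {
    resnums <- c(20, 70, 105,         # VL
                 120, 160, 200)       # CL
    mk(chain, resnums, aa_cycle(length(resnums)), "amino_acid", "CA", "C", row)
  }
  glycan <- function(chain, row) {
    mk(chain, 1:4, c("NAG", "NAG", "BMA", "MAN"), "monosaccharide", "C1", "C", row)
  }
  rbind(light("A", 0), heavy("B", 1), light("C", 2), heavy("D", 3),
        glycan("E", 4), glycan("F", 5))
}

# candidate planted sites per mode under the default region map
mode_site_pool <- function(mode, skeleton) {
  reg <- assign_regions_df(skeleton)
  pool <- switch(mode,
    FAB   = reg[region_group(reg$region) %in% "Fab", ],
    MODE1 = reg[region_group(reg$region) %in% "Fc", ],
    MODE2 = reg[reg$region %in% "hinge", ],
    MODE3 = reg[region_group(reg$region) %in% "Fc", ]
  )
  pool[, c("chain", "resnum", "region")]
}

# region-annotate a bare atom table using the default map + glycan rule
assign_regions_df <- function(atoms) {
  map <- default_region_map()
  reg <- ifelse(atoms$kind == "amino_acid", "unassigned", NA_character_)
  for (i in seq_len(nrow(map))) {
    hit <- atoms$chain == map$chain[i] &
      atoms$resnum >= map$start[i] & atoms$resnum <= map$end[i] &
      atoms$kind == "amino_acid"
    reg[hit] <- map$region[i]
  }
  reg[atoms$kind == "monosaccharide"] <- "glycan"
  atoms$region <- reg
  atoms
}

#' Generate a toy antibody-ssDNA complex with planted contacts
#'
#' Builds a simplified receptor (CA-only amino acids on a lattice covering
#' VH/CH1/hinge/CH2/CH3 on heavy chains B/D, VL/CL on light chains A/C, and
#' NAG/BMA/MAN glycan chains E/F) and places ligand nucleotides (single-P
#' residues, chain Z) so that exactly the planted sites fall within the
#' default contact cutoff; every other ligand-receptor atom pair is at least
#' 2 Angstrom beyond it. For `planted_mode = "MODE3"` roughly 70 percent of
#' the planted sites are drawn from Fc and the rest from CH1/CL.
#'
#' @param spec A [complex_spec()].
#' @return List with `structure` (a region-annotated `complex_structure`) and
#'   `truth` (data frame `chain`, `resnum` of the planted receptor sites).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "complex_spec"))
  skeleton <- toy_receptor_skeleton(spec$spacing)
  with_seed(spec$seed, {
    sites <- spec$planted_contact_sites
    if (is.null(sites)) {
      n_sites <- min(spec$n_nucleotides, 3L + sample.int(3L, 1L))
      if (spec$planted_mode == "MODE3") {
        n_fc <- max(ceiling(0.7 * n_sites), ceiling(0.5 * n_sites) + 1L)
        n_fab <- n_sites - n_fc
        if (n_fab < 1L) { n_fab <- 1L; n_fc <- n_sites - 1L }
        fc_pool <- mode_site_pool("MODE1", skeleton)
        fab_pool <- assign_regions_df(skeleton)
        fab_pool <- fab_pool[fab_pool$region %in% c("CH1", "CL"), c("chain", "resnum", "region")]
        sites <- rbind(fc_pool[sample.int(nrow(fc_pool), n_fc), ],
                       fab_pool[sample.int(nrow(fab_pool), n_fab), ])
      } else {
        pool <- mode_site_pool(spec$planted_mode, skeleton)
        sites <- pool[sample.int(nrow(pool), min(n_sites, nrow(pool))), ]
      }
      sites <- sites[, c("chain", "resnum")]
    } else {
      sites <- as.data.frame(sites)[, c("chain", "resnum")]
      reg <- assign_regions_df(skeleton)
      ok <- paste(sites$chain, sites$resnum) %in% paste(reg$chain, reg$resnum)
      if (!all(ok)) {
        stop(sprintf("planted site(s) not in toy receptor: %s",
                     paste(paste0(sites$chain, ":", sites$resnum)[!ok], collapse = ", ")))
      }
      check <- check_sites_vs_mode(sites, spec$planted_mode, skeleton)
      if (!check$ok) stop(sprintf("impossible spec: %s", check$why))
    }
    if (nrow(sites) > spec$n_nucleotides) {
      stop("impossible spec: more planted sites than nucleotides")
    }

    base_cycle <- rep(c("DG", "DT", "DA", "DC"), length.out = spec$n_nucleotides)
    lig <- data.frame(
      chain = "Z", resnum = seq_len(spec$n_nucleotides),
      resname = base_cycle, atom = "P", element = "P",
      x = NA_real_, y = NA_real_, z = NA_real_,
      kind = "nucleotide", region = NA_character_, stringsAsFactors = FALSE
    )
    # one nucleotide per planted site, offset vertically off the lattice plane
    for (k in seq_len(nrow(sites))) {
      at <- skeleton[skeleton$chain == sites$chain[k] &
                       skeleton$resnum == sites$resnum[k], ]
      lig$x[k] <- at$x; lig$y[k] <- at$y; lig$z[k] <- spec$contact_distance
    }
    # remaining nucleotides parked far from everything
    extra <- which(is.na(lig$x))
    if (length(extra)) {
      lig$x[extra] <- 300 + seq_along(extra) * spec$spacing
      lig$y[extra] <- -300
      lig$z[extra] <- 0
    }
    atoms <- rbind(skeleton, lig)
    atoms <- atoms[, c("chain", "resnum", "resname", "atom", "element",
                       "x", "y", "z", "kind", "region")]
    st <- structure(list(
      complex_id = sprintf("toy_seed%d_%s", spec$seed, spec$planted_mode),
      atoms = atoms, ligand_chain = "Z",
      receptor_chains = c("A", "B", "C", "D"), glycan_chains = c("E", "F")
    ), class = "complex_structure")
    st <- assign_regions(st)
    list(structure = st,
         truth = data.frame(chain = sites$chain, resnum = sites$resnum,
                            stringsAsFactors = FALSE))
  })
}

check_sites_vs_mode <- function(sites, mode, skeleton) {
  reg <- assign_regions_df(skeleton)
  r <- reg$region[match(paste(sites$chain, sites$resnum),
                        paste(reg$chain, reg$resnum))]
  g <- region_group(r)
  ok <- switch(mode,
    FAB   = all(g %in% "Fab"),
    MODE1 = all(g %in% "Fc"),
    MODE2 = any(g %in% "hinge"),
    MODE3 = mean(g %in% "Fc") >= 0.5 && all(g %in% "Fc" | r %in% c("CH1", "CL")) &&
            any(!(g %in% "Fc"))
  )
  list(ok = ok, why = sprintf("planted sites inconsistent with mode %s", mode))
}

#' Generate an ensemble of toy complexes plus a pose-score table
#'
#' Mode counts are the largest-remainder rounding of `n * mode_proportions`.
#' Docking scores are drawn uniformly on \[16, 33\] (an arbitrary span typical
#' of rigid-docking scores for these systems) under the given seed.
#'
#' @param n Number of complexes (> 0).
#' @param mode_proportions Named numeric vector over
#'   FAB/MODE1/MODE2/MODE3 summing to 1.
#' @param seed Integer seed.
#' @return List with `complexes` (list of `make_toy_complex()` results, one
#'   per ligand, ids `SYN001`...) and `poses` (data frame `ligand_id`,
#'   `pose_rank`, `zdock_score`, plus the planted `mode`).
#' @export
make_ensemble <- function(n, mode_proportions = c(FAB = 0.3, MODE1 = 0.35,
                                                  MODE2 = 0.15, MODE3 = 0.2),
                          seed = 1) {
  if (!is.numeric(n) || n <= 0) stop("n must be a positive count")
  if (abs(sum(mode_proportions) - 1) > 1e-8) stop("mode proportions must sum to 1")
  stopifnot(all(names(mode_proportions) %in% c("FAB", "MODE1", "MODE2", "MODE3")))
  # largest-remainder apportionment
  quota <- n * mode_proportions
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  modes <- rep(names(counts), counts)

  with_seed(seed, {
    sub_seeds <- sample.int(2^31 - 2, n)
    scores <- round(stats::runif(n, 16, 33), 2)
    complexes <- vector("list", n)
    ids <- sprintf("SYN%03d", seq_len(n))
    for (i in seq_len(n)) {
      cx <- make_toy_complex(complex_spec(seed = sub_seeds[i],
                                          planted_mode = modes[i]))
      cx$structure$complex_id <- ids[i]
      complexes[[i]] <- cx
    }
    poses <- data.frame(ligand_id = ids, pose_rank = 1L, zdock_score = scores,
                        mode = modes, stringsAsFactors = FALSE)
    list(complexes = complexes, poses = poses)
  })
}

#' Specification of a synthetic sensorgram
#'
#' Defaults mirror the BLI assay design the package targets: a five-step
#' two-fold IgG concentration series from 0.0125 to 0.2 mg/mL, 300 s
#' association and dissociation phases, 30 s baselines, 5 Hz would be
#' realistic but 1 Hz sampling keeps fixtures small.
#'
#' @param seed Integer seed.
#' @param k_on,k_dis,R_max True kinetic parameters (1/(M s), 1/s, nm).
#' @param concentrations Analyte series in mg/mL.
#' @param molar_mass Analyte molar mass in g/mol.
#' @param noise_sd Gaussian noise standard deviation in nm (>= 0).
#' @param drift Linear drift in nm/s (default 0).
#' @param t_baseline,t_assoc,t_dissoc Phase durations in s (default 30/300/300).
#' @param dt Sampling interval in s.
#' @param regeneration Include 30 s regeneration steps (parsed but never
#'   fitted)?
#' @return List of class `sensorgram_spec`.
#' @export
sensorgram_spec <- function(seed = 1, k_on = 9.52e3, k_dis = 2.29e-3,
                            R_max = 0.25,
                            concentrations = c(0.0125, 0.025, 0.05, 0.1, 0.2),
                            molar_mass = 150000, noise_sd = 0.005, drift = 0,
                            t_baseline = 30, t_assoc = 300, t_dissoc = 300,
                            dt = 1, regeneration = FALSE) {
  stopifnot(k_on > 0, k_dis >= 0, R_max > 0, noise_sd >= 0,
            all(concentrations > 0), t_assoc > 0, t_dissoc > 0, dt > 0)
  structure(as.list(environment()), class = "sensorgram_spec")
}

#' Simulate a multi-cycle 1:1 sensorgram
#'
#' Per concentration: baseline, association, dissociation (and optionally
#' regeneration) phases generated from the closed-form 1:1 model, with i.i.d.
#' Gaussian noise and optional linear drift added on top. With
#' `noise_sd = 0` and `drift = 0` the trace equals [langmuir_response()]
#' exactly. Deterministic for a given spec.
#'
#' @param spec A [sensorgram_spec()].
#' @param ligand_id Identifier attached to the trace.
#' @return Object of class `sensorgram`: list with `ligand_id` and `steps`,
#'   each step a list with `phase`, `conc_mg_ml`, `conc_molar`, `times`
#'   (absolute s), `responses` (nm).
#' @export
simulate_sensorgram <- function(spec, ligand_id = "synthetic") {
  stopifnot(inherits(spec, "sensorgram_spec"))
  with_seed(spec$seed, {
    steps <- list()
    t0 <- 0
    noisy <- function(r, times) {
      r <- r + spec$drift * times
      if (spec$noise_sd > 0) r <- r + stats::rnorm(length(r), 0, spec$noise_sd)
      r
    }
    add_step <- function(phase, conc_mg, resp_fun, dur) {
      times <- seq(0, dur, by = spec$dt)
      abs_t <- t0 + times
      conc_m <- if (conc_mg > 0) mg_per_ml_to_molar(conc_mg, spec$molar_mass) else 0
      steps[[length(steps) + 1L]] <<- list(
        phase = phase, conc_mg_ml = conc_mg, conc_molar = conc_m,
        times = abs_t, responses = noisy(resp_fun(times, conc_m), abs_t)
      )
      t0 <<- abs_t[length(abs_t)] + spec$dt
    }
    for (cmg in spec$concentrations) {
      add_step("baseline", 0, function(t, C) rep(0, length(t)), spec$t_baseline)
      add_step("association", cmg, function(t, C) {
        langmuir_response(t, C, spec$k_on, spec$k_dis, spec$R_max, "association")
      }, spec$t_assoc)
      r0 <- langmuir_response(spec$t_assoc, mg_per_ml_to_molar(cmg, spec$molar_mass),
                              spec$k_on, spec$k_dis, spec$R_max, "association")
      add_step("dissociation", 0, function(t, C) {
        langmuir_response(t, 0, spec$k_on, spec$k_dis, spec$R_max,
                          "dissociation", R0 = r0)
      }, spec$t_dissoc)
      if (spec$regeneration) {
        add_step("regeneration", 0, function(t, C) rep(0, length(t)), 30)
      }
    }
    structure(list(ligand_id = ligand_id, steps = steps), class = "sensorgram")
  })
}

#' @export
print.sensorgram <- function(x, ...) {
  phases <- vapply(x$steps, `[[`, character(1), "phase")
  cat(sprintf("<sensorgram> %s: %d steps (%s)\n", x$ligand_id, length(x$steps),
              paste(rle(phases)$values, collapse = "/")))
  invisible(x)
}

#' Simulate an SPA-competition trace
#'
#' Loading (SPA on the sensor), IgG-capture association rising to
#' `capture_response`, then a ligand-challenge association step whose signal
#' ramps linearly by `challenge_delta` nm (0 for a non-competing ligand),
#' with Gaussian noise throughout.
#'
#' @param seed Integer seed.
#' @param capture_response IgG capture plateau in nm.
#' @param challenge_delta Net signal change during the ligand challenge in nm;
#'   negative values model displacement of the captured antibody.
#' @param noise_sd Gaussian noise sd in nm.
#' @param t_step Step duration in s.
#' @param dt Sampling interval in s.
#' @return A `sensorgram` with loading, association (capture) and association
#'   (challenge) steps.
#' @export
simulate_competition <- function(seed = 1, capture_response = 0.5,
                                 challenge_delta = 0, noise_sd = 0.002,
                                 t_step = 300, dt = 1) {
  with_seed(seed, {
    mk_times <- function(t0) t0 + seq(0, t_step, by = dt)
    noisy <- function(r) if (noise_sd > 0) r + stats::rnorm(length(r), 0, noise_sd) else r
    t1 <- mk_times(0)
    load <- list(phase = "loading", conc_mg_ml = 0, conc_molar = 0, times = t1,
                 responses = noisy(0.3 * (1 - exp(-(t1 - t1[1]) / 30))))
    t2 <- mk_times(t1[length(t1)] + dt)
    capt <- list(phase = "association", conc_mg_ml = 0.2,
                 conc_molar = mg_per_ml_to_molar(0.2),
                 times = t2,
                 responses = noisy(capture_response * (1 - exp(-(t2 - t2[1]) / 60))))
    t3 <- mk_times(t2[length(t2)] + dt)
    base_level <- capture_response * (1 - exp(-t_step / 60))
    chal <- list(phase = "association", conc_mg_ml = 0, conc_molar = 5e-7,
                 times = t3,
                 responses = noisy(base_level + challenge_delta *
                                     (t3 - t3[1]) / t_step))
    structure(list(ligand_id = "competition", steps = list(load, capt, chal)),
              class = "sensorgram")
  })
}
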