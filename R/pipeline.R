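## Thin pipeline layer: validated run configuration, subcommand dispatch and
## machine-readable artifacts. The Rscript wrapper in inst/cli/hexbind.R
## forwards shell arguments here.

#' Run configuration
#'
#' Validated bundle of the tunable cutoffs and solver settings, with the
#' documented defaults. Precedence is CLI flag > config file > default; the
#' configuration hash is embedded in every artifact for provenance.
#'
#' @param temperature Kelvin (default 300).
#' @param hb_cutoff,pi_cutoff,contact_cutoff,zinc_cutoff Angstroms.
#' @param wham_bins,wham_tol,wham_max_iter WHAM settings.
#' @param seed Integer seed for any stochastic step.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(temperature = 300, hb_cutoff = HB_CUTOFF,
                       pi_cutoff = PI_CUTOFF, contact_cutoff = CONTACT_CUTOFF,
                       zinc_cutoff = ZN_CUTOFF, wham_bins = 100,
                       wham_tol = 1e-8, wham_max_iter = 1e5, seed = 1,
                       out_dir = ".") {
  cfg <- list(temperature = temperature, hb_cutoff = hb_cutoff,
              pi_cutoff = pi_cutoff, contact_cutoff = contact_cutoff,
              zinc_cutoff = zinc_cutoff, wham_bins = wham_bins,
              wham_tol = wham_tol, wham_max_iter = wham_max_iter,
              seed = as.integer(seed), out_dir = out_dir)
  cuts <- unlist(cfg[c("hb_cutoff", "pi_cutoff", "contact_cutoff", "zinc_cutoff")])
  if (any(cuts <= 0)) abort("all cutoffs must be positive")
  if (temperature <= 0) abort("temperature must be positive")
  if (wham_bins < 2 || wham_tol <= 0 || wham_max_iter < 1) {
    abort("invalid WHAM settings")
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run one pipeline subcommand
#'
#' Dispatches to the package functions and writes deterministic JSON (and,
#' where tabular, TSV) artifacts into `config$out_dir`. Subcommands:
#' `classify`, `zinc`, `sites`, `contacts` (one structure path),
#' `rmsd` (two structure paths; `args$selection` = "backbone" or "all"),
#' `ti` (lambda-series file), `wham` (windows directory; `args$plateau` =
#' length-2 range), `kd` (`args$dg`), `decompose` (`args$w0`, `args$symm`,
#' `args$vol`), `fit-hill` (titration CSV).
#'
#' @param subcommand Subcommand name.
#' @param inputs Character vector of input paths (as each subcommand needs).
#' @param config A [run_config()].
#' @param args Named list of subcommand-specific options.
#' @return The result object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(subcommand, inputs = character(), config = run_config(),
                         args = list()) {
  if (!inherits(config, "run_config")) abort("config must be a run_config()")
  result <- switch(subcommand,
    classify = {
      st <- read_structure(inputs[1])
      cl <- classify_states(st)
      out <- mutate(cl$monomers, hexamer_state = cl$hexamer_state)
      write_artifact(out, config, "classify")
      out
    },
    zinc = {
      st <- read_structure(inputs[1])
      zn <- classify_zinc_site(st, cutoff = config$zinc_cutoff)
      write_artifact(select(zn, -"ligands"), config, "zinc")
      zn
    },
    sites = {
      st <- read_structure(inputs[1])
      ls_ <- assign_ligand_sites(st, contact_cutoff = config$contact_cutoff)
      write_artifact(select(ls_, -"contacts"), config, "sites")
      ls_
    },
    contacts = {
      st <- read_structure(inputs[1])
      ct <- detect_contacts(st, hb_cutoff = config$hb_cutoff,
                            pi_cutoff = config$pi_cutoff)
      write_artifact(ct, config, "contacts")
      ct
    },
    rmsd = {
      sel <- args$selection %||% "backbone"
      xa <- selection_coords(read_structure(inputs[1]), sel)
      xb <- selection_coords(read_structure(inputs[2]), sel)
      sp <- superpose(xa, xb)
      out <- tibble(rmsd = sp$rmsd, n_atoms = sp$n_atoms, selection = sel)
      write_artifact(out, config, "rmsd")
      out
    },
    ti = {
      res <- ti_integrate(read_lambda_series(inputs[1]))
      write_artifact(res, config, "ti")
      res
    },
    wham = {
      uw <- read_umbrella_windows(inputs[1], temperature = config$temperature)
      pmf <- wham_pmf(uw, n_bins = config$wham_bins, tol = config$wham_tol,
                      max_iter = config$wham_max_iter,
                      plateau_range = args$plateau)
      write_artifact(pmf$profile, config, "wham")
      pmf
    },
    kd = {
      dg <- args$dg %||% abort("kd subcommand needs args$dg")
      out <- tibble(dg = dg, temperature = config$temperature,
                    kd = dg_to_kd(dg, config$temperature))
      write_artifact(out, config, "kd")
      out
    },
    decompose = {
      out <- combine_binding(args$w0, args$symm, args$vol,
                             temperature = config$temperature)
      write_artifact(as_tibble(out), config, "decompose")
      out
    },
    `fit-hill` = {
      tab <- as_tibble(utils::read.csv(inputs[1]))
      fits <- fit_hill_replicates(tab, init = args$init)
      write_artifact(fits, config, "fit_hill")
      fits
    },
    abort(paste0("unknown subcommand '", subcommand, "'"))
  )
  invisible(result)
}

selection_coords <- function(structure, selection = "backbone") {
  at <- as_atoms(structure, model = 1L)
  if (selection == "backbone") {
    at <- filter(at, .data$record == "ATOM",
                 .data$atom_name %in% c("N", "CA", "C", "O"))
  } else if (selection == "ligand") {
    at <- filter(at, .data$record == "HETATM",
                 !.data$resid %in% NON_LIGAND_HET)
  }
  at[, c("x", "y", "z")]
}

## JSON (always) + TSV (tabular) artifact writer; no timestamps, so re-runs
## with identical config + inputs are byte-identical.
write_artifact <- function(x, config, name) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(tool = "hexbind", subcommand = name,
                  config_hash = config_hash(config), seed = config$seed,
                  result = as.data.frame(x))
  jsonlite::write_json(payload, file.path(config$out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.data.frame(x)) {
    utils::write.table(as.data.frame(x),
                       file.path(config$out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
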