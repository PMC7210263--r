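#' Generation campaign configuration
#'
#' Bundles every tunable of a generation run: the level of theory passed
#' through to the engine, enumeration constraints, verification thresholds,
#' perception tolerance, conformer count and the campaign seed.
#'
#' @param method,basis Level-of-theory strings (e.g. `"B97-D3"`,
#'   `"def2-mSVP"` or `"wB97X-D3"`, `"def2-TZVP"`).
#' @param constraints [driving_constraints()].
#' @param imag_magnitude_min Imaginary-frequency magnitude cutoff, cm^-1.
#' @param drift_tol TS-optimization energy-drift tolerance, kcal/mol.
#' @param perceive_tol Covalent-radius scale factor for connectivity
#'   perception.
#' @param n_conformers Seeded embedding starts per reactant.
#' @param retain_k Duplicates of the same reaction retained for TS
#'   optimization.
#' @param seed Campaign seed (drives the mock executor and all embeddings).
#' @return A `generation_config` list.
#' @export
generation_config <- function(method = "B97-D3", basis = "def2-mSVP",
                              constraints = driving_constraints(),
                              imag_magnitude_min = 100, drift_tol = 3.0,
                              perceive_tol = 1.2, n_conformers = 5L,
                              retain_k = 4L, seed = 1L) {
  structure(list(method = method, basis = basis, constraints = constraints,
                 imag_magnitude_min = imag_magnitude_min,
                 drift_tol = drift_tol, perceive_tol = perceive_tol,
                 n_conformers = as.integer(n_conformers),
                 retain_k = as.integer(retain_k), seed = as.integer(seed)),
            class = "generation_config")
}

config_level <- function(config) paste(config$method, config$basis, sep = "/")

#' Prepare a reactant from SMILES
#'
#' Parses the SMILES, embeds `n_conformers` seeded conformers, relaxes each
#' and selects the lowest-stress structure, and assembles the opt+freq
#' engine job. Deterministic given `seed`.
#'
#' @param smiles Reactant SMILES over H/C/N/O.
#' @param config A [generation_config()].
#' @param seed Seed (defaults to the config seed).
#' @return List with `smiles`, `graph`, `geometry` and `job`.
#' @export
prepare_reactant <- function(smiles, config = generation_config(),
                             seed = config$seed) {
  g <- tryCatch(mol_from_smiles(smiles),
                rxnforge_smiles_parse = function(e) {
                  stop_rxn("preparation", paste0("unparsable SMILES: ", smiles))
                })
  geom <- embed_geometry(g, seed = derive_seed(seed, paste0("prep|", smiles)),
                         n_conformers = config$n_conformers)
  cfg <- engine_config(config$method, config$basis, "opt+freq")
  job <- list(
    type = "opt_freq",
    key = paste0("opt|", config_level(config), "|", smiles),
    input = write_engine_input(g$elements, geom, cfg),
    meta = list(graph = g, geometry = geom, level = config_level(config))
  )
  list(smiles = smiles, graph = g, geometry = geom, job = job)
}

#' Retain up to k duplicate candidates per reaction
#'
#' Duplicate discoveries of the same reaction (same [reaction_key()]) are
#' not all discarded: the `k` lowest-provisional-barrier candidates per key
#' are kept for TS optimization in case some optimizations fail. Ties break
#' by discovery order.
#'
#' @param candidates Tibble with columns `key` and `provisional_barrier`
#'   (kcal/mol), in discovery order.
#' @param k Maximum retained per key.
#' @return The retained subset, original order preserved.
#' @export
retain_candidates <- function(candidates, k = 4L) {
  if (nrow(candidates) == 0) return(candidates)
  candidates |>
    dplyr::mutate(.disc = dplyr::row_number()) |>
    dplyr::group_by(.data$key) |>
    dplyr::arrange(.data$provisional_barrier, .data$.disc, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.disc) |>
    dplyr::select(-".disc")
}

#' Final duplicate removal: lowest barrier wins
#'
#' One record per reaction key, the minimum-`ea` one (ties by first
#' occurrence); idempotent; output order follows the input order of the
#' retained records.
#'
#' @param records Tibble with columns `key` and `ea`.
#' @return Deduplicated tibble.
#' @export
dedup_final <- function(records) {
  if (nrow(records) == 0) return(records)
  records |>
    dplyr::mutate(.disc = dplyr::row_number()) |>
    dplyr::group_by(.data$key) |>
    dplyr::arrange(.data$ea, .data$.disc, .by_group = TRUE) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.disc) |>
    dplyr::select(-".disc")
}

#' Canonical reaction key
#'
#' Reactant identity key plus the sorted multiset of product fragment
#' identity keys; order-independent for products.
#'
#' @param reactant_key Reactant identity key string.
#' @param product_keys Character vector of product fragment keys.
#' @return Single key string.
#' @export
reaction_key <- function(reactant_key, product_keys) {
  paste0(reactant_key, ">>", paste(sort(product_keys), collapse = "."))
}

stage_cached <- function(state_dir, name, compute) {
  if (is.null(state_dir)) return(compute())
  path <- file.path(state_dir, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- compute()
  dir.create(state_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(val, path)
  val
}

#' Run a full generation campaign
#'
#' Executes the stages in order: reactant preparation, driving-coordinate
#' enumeration, path search (executor), product optimization (executor),
#' duplicate-candidate retention, TS optimization (executor), perception,
#' verification, energetics, final dedup and dataset assembly. Failed
#' executor jobs are data (the candidate is dropped and counted), never
#' errors. With the mock executor and a fixed seed the result is
#' bit-reproducible; with `state_dir` set, each stage's result is cached on
#' disk so an interrupted campaign resumes where it stopped.
#'
#' @param smiles_list Character vector of reactant SMILES.
#' @param config A [generation_config()].
#' @param executor An executor function (e.g. [mock_executor()]).
#' @param state_dir Optional directory for stage-resumable state.
#' @param only_sets Optional tibble (`reactant_smiles`, `dc_signature`)
#'   restricting the path searches to the listed driving-coordinate sets;
#'   used by [refine_pass()] to re-optimize only already-discovered
#'   pathways.
#' @return A `generation_result`: list with `dataset` (final deduplicated
#'   records, CSV columns first), `candidates` (extracted records before
#'   final dedup, verification outcomes included), `counts` (per-stage
#'   bookkeeping) and `config`.
#' @export
run_generation <- function(smiles_list, config = generation_config(),
                           executor = mock_executor(config$seed),
                           state_dir = NULL, only_sets = NULL) {
  lvl <- config_level(config)
  seed <- config$seed

  reactants <- stage_cached(state_dir, "01_reactants", function() {
    lapply(smiles_list, function(smi) {
      prep <- tryCatch(prepare_reactant(smi, config),
                       rxnforge_error = function(e) NULL)
      if (is.null(prep)) return(list(smiles = smi, status = "prep_failed"))
      res <- executor(prep$job)
      if (res$status != "ok") return(list(smiles = smi, status = "opt_failed"))
      rec <- parse_optfreq_log(res$output)
      if (!check_minimum(rec)) {
        return(list(smiles = smi, status = "not_minimum"))
      }
      list(smiles = smi, status = "ok", graph = prep$graph, optfreq = rec,
           log = res$output, key = identity_key(prep$graph))
    })
  })

  live <- Filter(function(r) identical(r$status, "ok"), reactants)

  enums <- stage_cached(state_dir, "02_enumeration", function() {
    lapply(live, function(r) {
      enumerate_driving_coordinates(r$graph, config$constraints)
    })
  })

  paths <- stage_cached(state_dir, "03_paths", function() {
    out <- list()
    for (ri in seq_along(live)) {
      r <- live[[ri]]
      sets <- enums[[ri]]
      for (si in seq_len(nrow(sets))) {
        if (!is.null(only_sets) &&
            !any(only_sets$reactant_smiles == r$smiles &
                 only_sets$dc_signature == sets$signature[si])) next
        key <- sprintf("gsm|%s|%s|%s", lvl, r$smiles, sets$signature[si])
        job <- list(type = "string", key = key, input = NULL,
                    meta = list(reactant_graph = r$graph,
                                geometry = r$optfreq$geometry,
                                breaks = sets$breaks[[si]],
                                forms = sets$forms[[si]],
                                level = lvl))
        res <- executor(job)
        out[[length(out) + 1L]] <- list(
          reactant_idx = ri, set_idx = si, key = key,
          status = res$status,
          string = if (res$status == "ok") parse_string_output(res$output),
          string_log = if (res$status == "ok") res$output
        )
      }
    }
    out
  })

  products <- stage_cached(state_dir, "04_products", function() {
    lapply(paths, function(pt) {
      if (pt$status != "ok") return(list(status = "path_failed"))
      r <- live[[pt$reactant_idx]]
      ep <- pt$string$endpoint_geometry
      pg_formal <- apply_changes(r$graph,
                                 enums[[pt$reactant_idx]]$breaks[[pt$set_idx]],
                                 enums[[pt$reactant_idx]]$forms[[pt$set_idx]])
      job <- list(type = "opt_freq", key = paste0("popt|", pt$key),
                  input = NULL,
                  meta = list(graph = pg_formal, geometry = ep, level = lvl))
      res <- executor(job)
      if (res$status != "ok") return(list(status = "popt_failed"))
      rec <- parse_optfreq_log(res$output)
      pg <- tryCatch(
        perceive_connectivity(r$graph$elements, rec$geometry,
                              tol = config$perceive_tol,
                              charges = r$graph$charges),
        error = function(e) NULL)
      if (is.null(pg)) return(list(status = "perception_failed"))
      if (!is.null(connectivity_isomorphism(pg, r$graph))) {
        return(list(status = "no_reaction"))   # path relaxed back to reactant
      }
      frs <- fragments(pg)
      pkeys <- vapply(frs, identity_key, character(1))
      list(status = "ok", optfreq = rec, log = res$output, graph = pg,
           fragments = frs, product_keys = pkeys)
    })
  })

  cand_tbl <- {
    ok <- which(vapply(products, function(p) identical(p$status, "ok"), logical(1)))
    if (length(ok) == 0) {
      tibble::tibble(cand = integer(0), key = character(0),
                     provisional_barrier = numeric(0))
    } else {
      tibble::tibble(
        cand = ok,
        key = vapply(ok, function(i) {
          reaction_key(live[[paths[[i]]$reactant_idx]]$key,
                       products[[i]]$product_keys)
        }, character(1)),
        provisional_barrier = vapply(ok, function(i) {
          r <- live[[paths[[i]]$reactant_idx]]
          (max(paths[[i]]$string$node_energies) - r$optfreq$energy) * HARTREE_TO_KCAL
        }, numeric(1))
      )
    }
  }
  retained <- retain_candidates(cand_tbl, k = config$retain_k)

  ts_opts <- stage_cached(state_dir, "05_ts", function() {
    lapply(retained$cand, function(i) {
      pt <- paths[[i]]
      r <- live[[pt$reactant_idx]]
      job <- list(type = "ts_opt_freq", key = paste0("tsopt|", pt$key),
                  input = NULL,
                  meta = list(reactant_graph = r$graph,
                              product_graph = products[[i]]$graph,
                              geometry = pt$string$ts_geometry,
                              string_max_energy = max(pt$string$node_energies),
                              level = lvl))
      res <- executor(job)
      if (res$status != "ok") return(list(status = "ts_failed"))
      list(status = "ok", optfreq = parse_optfreq_log(res$output),
           log = res$output)
    })
  })

  extract <- stage_cached(state_dir, "06_extract", function() {
    rows <- list()
    for (q in seq_len(nrow(retained))) {
      i <- retained$cand[q]
      if (ts_opts[[q]]$status != "ok") next
      pt <- paths[[i]]
      r <- live[[pt$reactant_idx]]
      prod <- products[[i]]
      rsmi_p <- perceive_molecule(r$graph$elements, r$optfreq$geometry,
                                  tol = config$perceive_tol,
                                  charges = r$graph$charges)
      frs_p <- lapply(prod$fragments, function(fr) {
        pm <- list(graph = fr, orders = assign_bond_orders(fr))
        class(pm) <- "perceived_mol"
        pm
      })
      smis <- tryCatch(
        reaction_smiles(rsmi_p, frs_p, r$graph, prod$fragments),
        rxnforge_error = function(e) NULL)
      if (is.null(smis)) next
      report <- verify_reaction(
        r$optfreq, ts_opts[[q]]$optfreq, prod$optfreq,
        r$graph, prod$graph, pt$string,
        imag_magnitude_min = config$imag_magnitude_min,
        drift_tol = config$drift_tol)
      se_r <- species_energetics(r$optfreq, level = lvl)
      se_ts <- species_energetics(ts_opts[[q]]$optfreq, level = lvl)
      se_p <- species_energetics(prod$optfreq, level = lvl)
      ea <- suppressWarnings(activation_energy(se_r, se_ts))
      dh <- reaction_enthalpy(se_r, list(se_p))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rsmi = smis$rsmi, psmi = smis$psmi, ea = ea, dh = dh,
        level_tag = lvl, key = retained$key[q],
        reactant_smiles = r$smiles,
        dc_signature = enums[[pt$reactant_idx]]$signature[pt$set_idx],
        passed = report$passed,
        report = list(report),
        r_log = r$log, p_log = prod$log, ts_log = ts_opts[[q]]$log,
        string_log = pt$string_log,
        breaks = list(enums[[pt$reactant_idx]]$breaks[[pt$set_idx]]),
        forms = list(enums[[pt$reactant_idx]]$forms[[pt$set_idx]])
      )
    }
    dplyr::bind_rows(rows)
  })

  verified <- if (nrow(extract) > 0) extract[extract$passed, ] else extract
  final <- dedup_final(verified)
  if (nrow(final) > 0) {
    final$idx <- seq_len(nrow(final)) - 1L
    final <- dplyr::relocate(final, "idx", "rsmi", "psmi", "ea", "dh")
  } else {
    final <- tibble::tibble(idx = integer(0), rsmi = character(0),
                            psmi = character(0), ea = numeric(0),
                            dh = numeric(0))
  }
  n_path_ok <- sum(vapply(paths, function(p) identical(p$status, "ok"), logical(1)))
  structure(list(
    dataset = final,
    candidates = extract,
    counts = tibble::tibble(
      n_reactants = length(smiles_list),
      n_reactants_ok = length(live),
      n_driving_sets = sum(vapply(enums, nrow, integer(1))),
      n_paths_ok = n_path_ok,
      n_products_ok = nrow(cand_tbl),
      n_retained = nrow(retained),
      n_ts_ok = sum(vapply(ts_opts, function(t) identical(t$status, "ok"), logical(1))),
      n_extracted = nrow(extract),
      n_verified = nrow(verified),
      n_final = nrow(final)
    ),
    config = config
  ), class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat("<generation_result>", config_level(x$config), "\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  invisible(x)
}

#' Summarize a generation result
#'
#' @param x A `generation_result`.
#' @param ... Unused.
#' @return One-row tibble with stage counts and energy ranges.
#' @export
glance.generation_result <- function(x, ...) {
  dplyr::bind_cols(
    x$counts,
    tibble::tibble(
      ea_min = if (nrow(x$dataset)) min(x$dataset$ea) else NA_real_,
      ea_max = if (nrow(x$dataset)) max(x$dataset$ea) else NA_real_,
      dh_min = if (nrow(x$dataset)) min(x$dataset$dh) else NA_real_,
      dh_max = if (nrow(x$dataset)) max(x$dataset$dh) else NA_real_
    )
  )
}

#' Refine a generation result at a second level of theory
#'
#' Re-runs the engine-facing stages (path search, product and TS
#' optimization) for every candidate of the first pass at the new level,
#' re-extracts, re-verifies and re-deduplicates, so duplicates that reorder
#' in barrier height at the higher level resolve to the new lowest. Input
#' candidates (pre-dedup) are used so duplicate retention still pays off if
#' some reoptimizations fail.
#'
#' @param result A `generation_result` from the first pass.
#' @param config_b [generation_config()] for the refinement level.
#' @param executor Executor for the refinement jobs.
#' @param state_dir Optional stage-state directory.
#' @return A `generation_result` at the new level.
#' @export
refine_pass <- function(result, config_b,
                        executor = mock_executor(config_b$seed),
                        state_dir = NULL) {
  if (identical(config_level(result$config), config_level(config_b))) {
    warning("refinement level equals the first-pass level")
  }
  smiles <- unique(result$candidates$reactant_smiles)
  sets <- dplyr::distinct(result$candidates[, c("reactant_smiles", "dc_signature")])
  run_generation(smiles, config_b, executor, state_dir = state_dir,
                 only_sets = sets)
}

#' Write a dataset in the published layout
#'
#' A CSV with header exactly `idx,rsmi,psmi,ea,dh` plus one directory
#' `rxn%06d` per reaction containing `r%06d.log`, `p%06d.log` and
#' `ts%06d.log`; CSV row order equals directory order.
#'
#' @param records Final dataset tibble (needs the CSV columns and, for the
#'   log directories, `r_log`/`p_log`/`ts_log` text columns).
#' @param out_dir Output directory (created).
#' @param csv_name File name of the CSV.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(records, out_dir, csv_name = "reactions.csv") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- "idx,rsmi,psmi,ea,dh"
  if (nrow(records) > 0) {
    lines <- c(lines, sprintf("%d,%s,%s,%.6f,%.6f",
                              records$idx, records$rsmi, records$psmi,
                              records$ea, records$dh))
  }
  writeLines(lines, file.path(out_dir, csv_name))
  has_logs <- all(c("r_log", "p_log", "ts_log") %in% names(records))
  if (nrow(records) > 0) {
    if (!has_logs) {
      stop_rxn("packaging", "records carry no log provenance")
    }
    for (q in seq_len(nrow(records))) {
      logs <- list(r = records$r_log[q], p = records$p_log[q],
                   ts = records$ts_log[q])
      if (any(vapply(logs, function(t) is.na(t) || !nzchar(t), logical(1)))) {
        stop_rxn("packaging",
                 paste0("missing provenance log for reaction idx ",
                        records$idx[q]))
      }
      d <- file.path(out_dir, sprintf("rxn%06d", records$idx[q]))
      dir.create(d, showWarnings = FALSE)
      writeLines(logs$r, file.path(d, sprintf("r%06d.log", records$idx[q])))
      writeLines(logs$p, file.path(d, sprintf("p%06d.log", records$idx[q])))
      writeLines(logs$ts, file.path(d, sprintf("ts%06d.log", records$idx[q])))
    }
  }
  invisible(out_dir)
}

#' Write the TS-only collection (duplicates included)
#'
#' Every successfully optimized transition state, whether or not its
#' reaction survived verification and dedup, mirrors the published
#' with-duplicates TS archives.
#'
#' @param candidates Candidate tibble with `ts_log` texts.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_ts_collection <- function(candidates, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (q in seq_len(nrow(candidates))) {
    writeLines(candidates$ts_log[q],
               file.path(out_dir, sprintf("ts%06d.log", q - 1L)))
  }
  invisible(out_dir)
}

#' Read a dataset CSV written by [write_dataset()]
#'
#' @param path Path to the CSV.
#' @return Tibble with columns `idx`, `rsmi`, `psmi`, `ea`, `dh`.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
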