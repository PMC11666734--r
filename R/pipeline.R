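#' Pipeline configuration
#'
#' Bundles everything a case run needs: the shape model, the landmark file,
#' registration parameters, reconstruction tolerances and the output
#' directory. Paths are resolved at run time.
#'
#' @param model a `shape_model` or path to one saved with [save_model()].
#' @param landmarks a [landmark_set()], path to a landmark JSON, or `NULL`
#'   (skips clinical parameters).
#' @param reg_params a [nonrigid_params()].
#' @param max_outer,tol reconstruction loop controls (see
#'   [reconstruct_fracture()]).
#' @param remesh_edge if non-`NULL`, input meshes are remeshed to this
#'   isotropic edge length (mm) during preparation; 1.5 mm is the
#'   conventional choice for CT-derived hemipelvis surfaces.
#' @param units_scale multiplicative factor applied to mesh coordinates on
#'   read.
#' @param output_dir directory for per-case artefacts (`NULL`: no files).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(model, landmarks = NULL,
                            reg_params = nonrigid_params(),
                            max_outer = 5L, tol = 0.1,
                            remesh_edge = NULL, units_scale = 1,
                            output_dir = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (!inherits(model, "shape_model")) stop("model must be a shape_model or a path")
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  if (tol <= 0) stop("tol must be positive")
  structure(list(model = model, landmarks = landmarks, reg_params = reg_params,
                 max_outer = as.integer(max_outer), tol = as.numeric(tol),
                 remesh_edge = remesh_edge, units_scale = units_scale,
                 output_dir = output_dir),
            class = "pipeline_config")
}

prep_input <- function(x, config) {
  m <- if (is_triangle_mesh(x)) x else read_mesh(x, units_scale = config$units_scale)
  if (!is.null(config$remesh_edge)) m <- remesh_isotropic(m, config$remesh_edge)
  m
}

#' Run one reconstruction case end to end
#'
#' Executes the full workflow for a single fracture: read and prepare the
#' fragment mesh(es), merge, reconstruct through the shape model, and — when
#' an intact contralateral mesh is supplied — mirror and register it as
#' ground truth, compute whole-surface and plate-fitting-region RMSE, the
#' six clinical parameter differences and a per-vertex distance map. With an
#' output directory set, writes `reconstructed.ply`, `distance_map.ply`
#' (per-vertex `quality` scalar) and `report.json`. Fully deterministic:
#' re-running an identical case produces byte-identical artefacts.
#'
#' Stage failures are rethrown with the failing stage name prefixed.
#'
#' @param fragments mesh path(s) or [triangle_mesh()] object(s) of the
#'   fracture fragments.
#' @param config a [pipeline_config()].
#' @param contralateral optional intact opposite-side mesh or path.
#' @param case_id label for reports.
#' @param fracture_label free-text fracture classification carried through
#'   to reports (e.g. a Letournel type).
#' @return a `case_report` list.
#' @export
run_case <- function(fragments, config, contralateral = NULL,
                     case_id = "case", fracture_label = "") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is_triangle_mesh(fragments)) fragments <- list(fragments)
  if (is.character(fragments)) fragments <- as.list(fragments)
  frag_meshes <- stage("mesh_core.read_mesh",
                       lapply(fragments, prep_input, config = config))
  merged <- stage("mesh_core.merge_fragments", merge_fragments(frag_meshes))
  rec <- stage("reconstruction.reconstruct_fracture",
               reconstruct_fracture(config$model, merged,
                                    reg_params = config$reg_params,
                                    max_outer = config$max_outer,
                                    tol = config$tol))
  report <- list(case_id = case_id, fracture_label = fracture_label,
                 fraction_valid = rec$fraction_valid,
                 n_iterations = rec$n_iterations, converged = rec$converged,
                 warnings = character(0))
  dm <- NULL
  if (!is.null(contralateral)) {
    truth_mesh <- stage("mesh_core.read_mesh", prep_input(contralateral, config))
    truth <- stage("reconstruction.reconstruct_from_contralateral",
                   reconstruct_from_contralateral(config$model, truth_mesh,
                                                  reg_params = config$reg_params))
    report$rmse_whole_mm <- rmse(rec$reconstructed, truth)
    dm <- distance_map(rec$reconstructed, truth)
    if (!is.null(config$landmarks)) {
      lm <- config$landmarks
      report$rmse_platefit_mm <- rmse(rec$reconstructed, truth,
                                      indices = landmark_indices(lm))
      pr <- clinical_parameters(rec$reconstructed, lm)
      pt <- clinical_parameters(truth, lm)
      report$parameter_diffs <- as.list(compare_parameters(pr, pt))
    }
  }
  if (rec$fraction_valid < 0.25)
    report$warnings <- c(report$warnings, "fraction_valid below 0.25")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, paste0(case_id, "_", f))
    rec_mesh <- triangle_mesh(rec$reconstructed$coordinates,
                              config$model$template$faces, name = case_id)
    write_mesh(rec_mesh, out("reconstructed.ply"))
    if (!is.null(dm))
      write_mesh(rec_mesh, out("distance_map.ply"), quality = dm$per_vertex_distance)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  structure(c(report, list(result = rec, distance_map = dm)), class = "case_report")
}

case_row <- function(report) {
  data.frame(
    case_id = report$case_id,
    fracture_type = report$fracture_label,
    rmse_whole_mm = report$rmse_whole_mm %||% NA_real_,
    rmse_platefit_mm = report$rmse_platefit_mm %||% NA_real_,
    fraction_valid = report$fraction_valid,
    d_iliopectineal_length = report$parameter_diffs$iliopectineal_length %||% NA_real_,
    d_iliopectineal_radius = report$parameter_diffs$iliopectineal_radius %||% NA_real_,
    d_ischial_length = report$parameter_diffs$ischial_length %||% NA_real_,
    d_ischial_radius = report$parameter_diffs$ischial_radius %||% NA_real_,
    d_acetabular_diameter = report$parameter_diffs$acetabular_diameter %||% NA_real_,
    d_quadrilateral_slope = report$parameter_diffs$quadrilateral_slope %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Run a cohort of cases and summarise by fracture group
#'
#' Runs [run_case()] for every row of a case table, collects per-case
#' metrics into a data frame, and summarises each metric per fracture group
#' as median (IQR). With exactly two groups, group differences in each
#' metric are tested with the Mann-Whitney U test. With an output directory
#' set, writes `cases.csv` and `summary.csv`.
#'
#' @param cases data frame (or CSV path) with columns `case_id`,
#'   `fragments` (path, or several separated by `;`), optional
#'   `contralateral` and `group`.
#' @param config a [pipeline_config()].
#' @return list with `cases` (per-case data frame), `summary` (long data
#'   frame of group medians/IQRs), `tests` (Mann-Whitney results per metric,
#'   when two groups), `reports` (raw case reports).
#' @export
run_cohort <- function(cases, config) {
  if (is.character(cases)) cases <- utils::read.csv(cases, stringsAsFactors = FALSE)
  if (nrow(cases) == 0L) stop("empty case table")
  if (is.null(cases$group)) cases$group <- "all"
  reports <- lapply(seq_len(nrow(cases)), function(i) {
    frags <- strsplit(as.character(cases$fragments[i]), ";", fixed = TRUE)[[1]]
    ctl <- if (!is.null(cases$contralateral) && nzchar(cases$contralateral[i]))
      cases$contralateral[i] else NULL
    run_case(frags, config, contralateral = ctl,
             case_id = as.character(cases$case_id[i]),
             fracture_label = as.character(cases$group[i]))
  })
  df <- do.call(rbind, lapply(reports, case_row))
  metrics <- setdiff(names(df), c("case_id", "fracture_type"))
  groups <- unique(df$fracture_type)
  summary_rows <- list()
  for (g in groups) {
    for (m in metrics) {
      vals <- df[[m]][df$fracture_type == g]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) next
      s <- summarize_values(vals)
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(group = g, metric = m, n = length(vals), median = s$median,
                   q25 = s$q25, q75 = s$q75, stringsAsFactors = FALSE)
    }
  }
  summary_df <- do.call(rbind, summary_rows)
  tests <- NULL
  if (length(groups) == 2L) {
    tests <- lapply(stats::setNames(metrics, metrics), function(m) {
      a <- df[[m]][df$fracture_type == groups[1]]
      b <- df[[m]][df$fracture_type == groups[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) == 0L || length(b) == 0L) return(NULL)
      mann_whitney_u(a, b)
    })
    tests <- Filter(Negate(is.null), tests)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(config$output_dir, "cases.csv"), row.names = FALSE)
    utils::write.csv(summary_df, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
  }
  list(cases = df, summary = summary_df, tests = tests, reports = reports)
}
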