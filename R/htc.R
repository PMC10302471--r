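# High-throughput helpers: unique folder creation, extension-based file
# relocation, order-stable parallel dispatch, and external-calculator
# command assembly. Command assembly is deliberately separated from
# execution so workflows can be planned (and tested) on machines without
# any quantum-chemistry binaries.

# 128-bit random hex token drawn from a private RNG stream so user-visible
# RNG state is never disturbed.
.hexToken <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(NULL)  # reseed from time/pid entropy
  paste(sprintf("%02x", sample.int(256L, 16L, replace = TRUE) - 1L),
        collapse = "")
}

#' Create uniquely named folders
#'
#' Creates \code{n} new directories under \code{root}, each named by a
#' random 128-bit hex token. Names are collision-checked against existing
#' entries (and re-drawn on the improbable clash), so repeated and
#' concurrent invocations never collide.
#'
#' @param n number of folders (>= 1).
#' @param root parent directory (must be writable).
#' @return character vector of the n created paths; all exist on return.
#' @export
createUniqueFolders <- function(n, root = ".") {
  if (n < 1L) stop("n must be >= 1")
  if (!dir.exists(root)) stop(sprintf("root '%s' does not exist", root))
  if (file.access(root, mode = 2) != 0)
    stop(sprintf("root '%s' is not writable", root))
  out <- character(n)
  for (k in seq_len(n)) {
    repeat {
      path <- file.path(root, .hexToken())
      # dir.create is atomic: FALSE means someone else owns that name
      if (!dir.exists(path) && dir.create(path, showWarnings = FALSE)) break
    }
    out[k] <- path
  }
  out
}

#' Relocate files into individually created folders
#'
#' Every file named \code{*.extension} directly under \code{root} (or in
#' its subtree when \code{recursive = TRUE}) is moved into its own freshly
#' created, uniquely named directory, so each target directory holds
#' exactly one matching file.
#'
#' @param extension file extension without the dot, e.g. "smi".
#' @param root directory to scan.
#' @param recursive also collect matching files from subdirectories
#'   (default FALSE: top level only).
#' @return named character vector mapping each original file path to the
#'   directory now holding it (a bijection; empty when nothing matched).
#' @export
filesToDirs <- function(extension, root = ".", recursive = FALSE) {
  if (!dir.exists(root)) stop(sprintf("root '%s' does not exist", root))
  pat <- paste0("\\.", extension, "$")
  files <- list.files(root, pattern = pat, recursive = recursive,
                      full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) return(stats::setNames(character(0), character(0)))
  dirs <- createUniqueFolders(length(files), root)
  for (k in seq_along(files)) {
    dest <- file.path(dirs[k], basename(files[k]))
    if (!suppressWarnings(file.rename(files[k], dest))) {
      if (!file.copy(files[k], dest)) # cross-device fallback
        stop(sprintf("could not relocate '%s'", files[k]))
      unlink(files[k])
    }
  }
  stats::setNames(dirs, files)
}

#' Apply a function over independent tasks, in parallel
#'
#' Results are positionally aligned with the inputs and identical to
#' sequential execution for deterministic tasks, whatever the worker
#' count. A task that throws does not abort its siblings: its slot holds
#' the captured condition object (test with \code{inherits(x, "error")}).
#'
#' @param tasks list (or vector) of work items.
#' @param fun function applied to each item.
#' @param plan a [DispatchPlan-class]; \code{nWorkers} parallel workers
#'   (forked processes; 1 means plain sequential execution).
#' @return list of results, one per task, in task order.
#' @export
parallelMap <- function(tasks, fun, plan = DispatchPlan()) {
  wrapped <- function(x) tryCatch(fun(x), error = function(e) e)
  if (plan@nWorkers == 1L || .Platform$OS.type != "unix")
    return(lapply(tasks, wrapped))
  parallel::mclapply(tasks, wrapped, mc.cores = plan@nWorkers,
                     mc.preschedule = TRUE)
}

.ENGINES <- list(
  `gfn2-xtb` = function(input, cores)
    list(program = "xtb",
         args = c(input, "--gfn", "2", "--parallel", as.character(cores))),
  `gfn-ff` = function(input, cores)
    list(program = "xtb",
         args = c(input, "--gfnff", "--parallel", as.character(cores))),
  `scf-engine` = function(input, cores)
    list(program = "python",
         args = c(input, "--cores", as.character(cores)))
)

#' Assemble an external-calculator command line
#'
#' Builds the full command (program, method flags, core count, input file)
#' for a supported engine without running anything. Deterministic for
#' fixed inputs; the string form round-trips through shell tokenization.
#'
#' @param engine "gfn2-xtb", "gfn-ff" or "scf-engine".
#' @param inputFile path to the structure/input file (must exist).
#' @param cores parallel cores the calculation may use (>= 1).
#' @return list with \code{program}, \code{args} and the assembled
#'   \code{command} string.
#' @examples
#' \dontrun{assembleCalculatorCommand("gfn2-xtb", "mol.xyz", 4)$command}
#' @export
assembleCalculatorCommand <- function(engine, inputFile, cores = 1L) {
  if (!engine %in% names(.ENGINES))
    stop(sprintf("unknown engine '%s'; supported engines: %s", engine,
                 paste(names(.ENGINES), collapse = ", ")))
  if (!file.exists(inputFile))
    stop(sprintf("input file '%s' does not exist", inputFile))
  if (cores < 1L) stop("cores must be >= 1")
  spec <- .ENGINES[[engine]](inputFile, as.integer(cores))
  spec$command <- paste(c(spec$program, spec$args), collapse = " ")
  spec
}
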