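## Persistent RDKit helper process (JSON lines over stdin/stdout).
## Only standard cheminformatics primitives run there; every algorithm of
## the package itself is implemented in R.

.chemotif <- new.env(parent = emptyenv())
.chemotif$proc <- NULL
.chemotif$id <- 0L
.chemotif$buf <- ""

pythonBinary <- function() {
  py <- getOption("chemotif.python", "")
  if (!nzchar(py)) py <- Sys.getenv("CHEMOTIF_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter found; set options(chemotif.python=...)")
  py
}

backendScriptPath <- function() {
  p <- system.file("python", "chemtools.py", package = "chemotif")
  if (!nzchar(p)) stop("bundled chemtools.py not found")
  p
}

backendAlive <- function() {
  !is.null(.chemotif$proc) && .chemotif$proc$is_alive()
}

#' Start (or return) the RDKit helper process
#'
#' The helper is started lazily on first use; an explicit call is only
#' needed to fail fast with a clear message when python/RDKit is missing.
#'
#' @return Invisibly, the `processx` process handle.
#' @export
startBackend <- function() {
  if (backendAlive()) return(invisible(.chemotif$proc))
  .chemotif$proc <- processx::process$new(
    pythonBinary(), c("-u", backendScriptPath()),
    stdin = "|", stdout = "|", stderr = "|")
  .chemotif$buf <- ""
  res <- tryCatch(backendCall("ping", list()), error = function(e) e)
  if (inherits(res, "error")) {
    err <- tryCatch(paste(.chemotif$proc$read_error_lines(), collapse = "\n"),
                    error = function(e) "")
    stopBackend()
    stop("could not start RDKit helper (is python with rdkit available?)\n",
         conditionMessage(res), "\n", err)
  }
  invisible(.chemotif$proc)
}

#' Stop the RDKit helper process
#' @return Invisibly `NULL`.
#' @export
stopBackend <- function() {
  if (!is.null(.chemotif$proc)) {
    try(.chemotif$proc$kill(), silent = TRUE)
    .chemotif$proc <- NULL
  }
  invisible(NULL)
}

.readResponseLine <- function(timeout) {
  deadline <- Sys.time() + timeout
  repeat {
    nl <- regexpr("\n", .chemotif$buf, fixed = TRUE)
    if (nl > 0) {
      line <- substr(.chemotif$buf, 1L, nl - 1L)
      .chemotif$buf <- substr(.chemotif$buf, nl + 1L, nchar(.chemotif$buf))
      return(line)
    }
    if (!backendAlive())
      stop("RDKit helper process died: ",
           paste(tryCatch(.chemotif$proc$read_error_lines(),
                          error = function(e) ""), collapse = "\n"))
    .chemotif$proc$poll_io(200L)
    chunk <- .chemotif$proc$read_output()
    if (nzchar(chunk)) .chemotif$buf <- paste0(.chemotif$buf, chunk)
    if (Sys.time() > deadline) stop("timeout waiting for RDKit helper")
  }
}

backendCall <- function(op, args, timeout = 600) {
  if (!backendAlive() && op != "ping") startBackend()
  .chemotif$id <- .chemotif$id + 1L
  req <- c(list(id = .chemotif$id, op = op), args)
  line <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA, null = "null")
  .chemotif$proc$write_input(paste0(line, "\n"))
  resp <- jsonlite::fromJSON(.readResponseLine(timeout),
                             simplifyVector = FALSE)
  if (!isTRUE(resp$ok))
    stop("RDKit helper error in op '", op, "': ", resp$error)
  resp$result
}

## thin vectorised wrappers -------------------------------------------------

.aslist <- function(x) lapply(unname(x), identity)

bkStandardize <- function(smiles, keepStereo = TRUE)
  backendCall("standardize", list(smiles = .aslist(smiles),
                                  keep_stereo = keepStereo))

bkDescriptors <- function(smiles)
  backendCall("descriptors", list(smiles = .aslist(smiles)))

bkBasic <- function(smiles)
  backendCall("basic", list(smiles = .aslist(smiles)))

bkAnnotate <- function(smiles)
  backendCall("annotate", list(smiles = .aslist(smiles)))

bkFragment <- function(items)
  backendCall("fragment", list(items = items))

bkFuseSplit <- function(items)
  backendCall("fuse_split", list(items = items))

bkMotifToken <- function(items)
  backendCall("motif_token", list(items = items))

bkTokenInfo <- function(tokens)
  backendCall("token_info", list(tokens = .aslist(tokens)))

bkJoin <- function(items)
  backendCall("join", list(items = items))

bkCanonical <- function(smiles, stripStereo = FALSE)
  backendCall("canonical", list(smiles = .aslist(smiles),
                                strip_stereo = stripStereo))

bkFingerprint <- function(smiles, radius = 2L, nbits = 2048L)
  backendCall("fingerprint", list(smiles = .aslist(smiles),
                                  radius = radius, nbits = nbits))

bkScaffold <- function(smiles)
  backendCall("scaffold", list(smiles = .aslist(smiles)))

bkBricsFrags <- function(smiles)
  backendCall("brics_frags", list(smiles = .aslist(smiles)))

bkFGs <- function(smiles)
  backendCall("fgs", list(smiles = .aslist(smiles)))

bkRingSystems <- function(smiles)
  backendCall("ring_systems", list(smiles = .aslist(smiles)))

bkAssemble <- function(items)
  backendCall("assemble", list(items = items))

bkStereocenters <- function(smiles)
  backendCall("stereocenters", list(smiles = .aslist(smiles)))

bkAssignStereo <- function(items)
  backendCall("assign_stereo", list(items = items))

bkRenumber <- function(items)
  backendCall("renumber", list(items = items))
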