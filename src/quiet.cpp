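// OpenBabel writes parse warnings directly to the process stderr stream
// (outside R's message sink). These helpers temporarily redirect fd 2 to
// /dev/null around conversion calls so expected failures (e.g. sampled
// SMILES that cannot be kekulized) do not flood the console.

#include <Rcpp.h>
#include <unistd.h>
#include <fcntl.h>

static int saved_fd = -1;

// [[Rcpp::export(name = ".muteStderr")]]
void muteStderr() {
  if (saved_fd != -1) return;
  fflush(stderr);
  saved_fd = dup(2);
  int devnull = open("/dev/null", O_WRONLY);
  if (devnull != -1) {
    dup2(devnull, 2);
    close(devnull);
  }
}

// [[Rcpp::export(name = ".unmuteStderr")]]
void unmuteStderr() {
  if (saved_fd == -1) return;
  fflush(stderr);
  dup2(saved_fd, 2);
  close(saved_fd);
  saved_fd = -1;
}
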