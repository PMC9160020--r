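# Start a real server in a background R process on a random localhost port;
# returns the process handle and base URL. Callers kill the process.

start_test_server <- function(db_dir) {
  port <- httpuv::randomPort()
  px <- callr::r_bg(function(d, p) {
    library(aakmer)
    serve(d, port = p)
  }, args = list(d = db_dir, p = port))
  url <- sprintf("http://127.0.0.1:%d", port)
  ok <- FALSE
  for (i in 1:100) {
    ok <- tryCatch({client_info(url); TRUE}, error = function(e) FALSE)
    if (ok) break
    if (!px$is_alive())
      stop("server died during startup: ",
           paste(px$read_all_error_lines(), collapse = "\n"))
    Sys.sleep(0.1)
  }
  if (!ok) { px$kill(); stop("server did not come up") }
  list(px = px, url = url)
}

raw_post <- function(url, body) {
  h <- curl::new_handle()
  curl::handle_setopt(h, customrequest = "POST", postfields = body)
  curl::curl_fetch_memory(url, handle = h)
}
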