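// Compact Bayesian additive regression trees sampler.
//
// Sum-of-trees model with the standard priors: depth prior
// p(split at depth d) = alpha * (1 + d)^(-beta), normal leaf prior with
// scale 0.5/(k*sqrt(m)) on the rescaled outcome (3/(k*sqrt(m)) for probit),
// scaled-inverse-chi-squared noise prior for continuous outcomes, and probit
// data augmentation for binary outcomes. Tree structures move by
// Metropolis-Hastings grow/prune proposals with leaf means integrated out.
// The sampler records, for every kept posterior draw, the number of
// splitting rules using each variable; inclusion proportions are these
// counts over the total number of splits in the draw.
//
// Uses R's RNG, so results are reproducible through set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Node {
  bool active = false;
  bool leaf = true;
  int var = -1;       // split variable (internal nodes)
  int cut = -1;       // index into the variable's cutpoint grid
  int left = -1, right = -1, parent = -1;
  int depth = 0;
  double mu = 0.0;    // leaf value
};

struct Tree {
  std::vector<Node> nodes;
  Tree() { nodes.resize(1); nodes[0].active = true; }
  int add_node() {
    for (int i = 0; i < (int)nodes.size(); ++i)
      if (!nodes[i].active) { nodes[i] = Node(); nodes[i].active = true; return i; }
    nodes.push_back(Node());
    nodes.back().active = true;
    return (int)nodes.size() - 1;
  }
  std::vector<int> leaves() const {
    std::vector<int> out;
    for (int i = 0; i < (int)nodes.size(); ++i)
      if (nodes[i].active && nodes[i].leaf) out.push_back(i);
    return out;
  }
  // internal nodes whose two children are both leaves
  std::vector<int> nogs() const {
    std::vector<int> out;
    for (int i = 0; i < (int)nodes.size(); ++i) {
      const Node& nd = nodes[i];
      if (nd.active && !nd.leaf && nodes[nd.left].leaf && nodes[nd.right].leaf)
        out.push_back(i);
    }
    return out;
  }
  int locate(const arma::rowvec& x, const std::vector<arma::vec>& cuts) const {
    int i = 0;
    while (!nodes[i].leaf) {
      const Node& nd = nodes[i];
      i = (x[nd.var] <= cuts[nd.var][nd.cut]) ? nd.left : nd.right;
    }
    return i;
  }
};

static double log_split_prob(int depth, double alpha, double beta) {
  return std::log(alpha) - beta * std::log1p((double)depth);
}

// integrated log-likelihood of a leaf given residual sum s and count nl
static double leaf_loglik(double s, int nl, double sigma2, double smu2) {
  double denom = sigma2 + nl * smu2;
  return 0.5 * std::log(sigma2 / denom) +
         0.5 * smu2 * s * s / (sigma2 * denom);
}

// [[Rcpp::export]]
Rcpp::List bart_cpp(const arma::mat& X, const arma::vec& y_in, bool binary,
                    int n_trees, int n_burn, int n_post,
                    double alpha_t, double beta_t, double k,
                    double nu, double q, int numcut) {
  const int n = X.n_rows, p = X.n_cols;

  // cutpoint grids: evenly indexed unique observed values
  std::vector<arma::vec> cuts(p);
  for (int j = 0; j < p; ++j) {
    arma::vec v = arma::sort(arma::unique(X.col(j)));
    int m = v.n_elem;
    if (m > 1) v = v.subvec(0, m - 2);  // top value cannot split
    m = v.n_elem;
    if (m > numcut) {
      arma::vec g(numcut);
      for (int c = 0; c < numcut; ++c)
        g[c] = v[(int)std::floor((double)c * m / numcut)];
      v = arma::unique(g);
    }
    cuts[j] = v;
  }

  // outcome scaling and priors
  arma::vec y = y_in;
  double sigma2 = 1.0, lambda_s = 1.0, smu;
  if (binary) {
    smu = 3.0 / (k * std::sqrt((double)n_trees));
  } else {
    double ymin = y.min(), ymax = y.max();
    double range = std::max(ymax - ymin, 1e-12);
    y = (y - 0.5 * (ymin + ymax)) / range;  // into [-0.5, 0.5]
    smu = 0.5 / (k * std::sqrt((double)n_trees));
    double sd_hat = arma::stddev(y);
    sigma2 = sd_hat * sd_hat;
    lambda_s = sigma2 * R::qchisq(1.0 - q, nu, 1, 0) / nu;
  }
  const double smu2 = smu * smu;

  std::vector<Tree> trees(n_trees);
  arma::mat fits(n, n_trees, arma::fill::zeros);  // per-tree fitted values
  arma::vec total_fit(n, arma::fill::zeros);
  arma::vec z = binary ? arma::vec(n, arma::fill::zeros) : y;  // latent

  arma::imat varcount(n_post, p, arma::fill::zeros);
  arma::vec sigma_draws(n_post, arma::fill::zeros);

  std::vector<int> leaf_of(n);

  for (int iter = 0; iter < n_burn + n_post; ++iter) {
    if (binary) {
      // probit augmentation: z_i ~ N(fit_i, 1) truncated by y_i
      for (int i = 0; i < n; ++i) {
        double m = total_fit[i];
        double u = R::runif(0.0, 1.0);
        if (y_in[i] > 0.5) {
          double lo = R::pnorm(0.0, m, 1.0, 1, 0);
          z[i] = R::qnorm(lo + u * (1.0 - lo), m, 1.0, 1, 0);
        } else {
          double hi = R::pnorm(0.0, m, 1.0, 1, 0);
          z[i] = R::qnorm(u * hi, m, 1.0, 1, 0);
        }
        if (!std::isfinite(z[i])) z[i] = (y_in[i] > 0.5) ? 1e-6 : -1e-6;
      }
    }

    for (int t = 0; t < n_trees; ++t) {
      Tree& tr = trees[t];
      // partial residual for this tree
      arma::vec r = z - total_fit + fits.col(t);

      // leaf membership and sufficient statistics
      for (int i = 0; i < n; ++i) leaf_of[i] = tr.locate(X.row(i), cuts);
      std::map<int, std::pair<double, int>> stat;  // leaf -> (sum, count)
      for (int i = 0; i < n; ++i) {
        auto& s = stat[leaf_of[i]];
        s.first += r[i]; s.second += 1;
      }

      bool grow = (R::runif(0.0, 1.0) < 0.5);
      std::vector<int> leaves = tr.leaves();
      std::vector<int> nogs = tr.nogs();
      if (tr.nodes[0].leaf) grow = true;  // cannot prune a stump

      if (grow) {
        int li = leaves[(int)std::floor(R::runif(0.0, 1.0) * leaves.size())];
        int var = (int)std::floor(R::runif(0.0, 1.0) * p);
        int ncut_var = (int)cuts[var].n_elem;
        int ci = ncut_var > 0
                     ? (int)std::floor(R::runif(0.0, 1.0) * ncut_var) : -1;
        double cval = ci >= 0 ? cuts[var][ci] : 0.0;
        double sl = 0, sr = 0; int nl = 0, nr = 0;
        if (ci >= 0) {
          for (int i = 0; i < n; ++i) {
            if (leaf_of[i] != li) continue;
            if (X(i, var) <= cval) { sl += r[i]; ++nl; } else { sr += r[i]; ++nr; }
          }
        }
        if (nl > 0 && nr > 0) {  // empty child or no cutpoints: reject
        auto st = stat[li];
        int d = tr.nodes[li].depth;
        double log_lik = leaf_loglik(sl, nl, sigma2, smu2) +
                         leaf_loglik(sr, nr, sigma2, smu2) -
                         leaf_loglik(st.first, st.second, sigma2, smu2);
        double lp_split = log_split_prob(d, alpha_t, beta_t);
        double lp_nosplit = std::log(1.0 - std::exp(lp_split));
        double lp_child_nosplit =
            2.0 * std::log(1.0 - std::exp(log_split_prob(d + 1, alpha_t, beta_t)));
        // the tree prior also charges 1/(p * ncut) for the chosen rule
        double log_prior = lp_split + lp_child_nosplit - lp_nosplit -
                           std::log((double)p) -
                           std::log((double)cuts[var].n_elem);
        // proposal: grow picks (leaf, var, cut); reverse prune picks a nog
        int n_nog_after = (int)tr.nogs().size();
        // growing a leaf whose parent was a nog keeps the nog count; else +1
        int par = tr.nodes[li].parent;
        bool parent_was_nog = false;
        if (par >= 0) {
          const Node& pn = tr.nodes[par];
          parent_was_nog = tr.nodes[pn.left].leaf && tr.nodes[pn.right].leaf;
        }
        n_nog_after += parent_was_nog ? 0 : 1;
        double log_prop =
            std::log((double)leaves.size()) + std::log((double)p) +
            std::log((double)cuts[var].n_elem) -
            std::log((double)n_nog_after);
        // growing from a stump is proposed with probability 1, not 1/2
        if (tr.nodes[0].leaf) log_prop += std::log(0.5);
        double log_alpha = log_lik + log_prior + log_prop;
        if (std::log(R::runif(0.0, 1.0)) < log_alpha) {
          int lc = tr.add_node(), rc = tr.add_node();
          Node& nd = tr.nodes[li];
          nd.leaf = false; nd.var = var; nd.cut = ci;
          nd.left = lc; nd.right = rc;
          tr.nodes[lc].parent = li; tr.nodes[rc].parent = li;
          tr.nodes[lc].depth = nd.depth + 1; tr.nodes[rc].depth = nd.depth + 1;
        }
        }
      } else if (!nogs.empty()) {
        int ni = nogs[(int)std::floor(R::runif(0.0, 1.0) * nogs.size())];
        Node& nd = tr.nodes[ni];
        double sl = 0, sr = 0; int nl = 0, nr = 0;
        for (int i = 0; i < n; ++i) {
          if (leaf_of[i] == nd.left) { sl += r[i]; ++nl; }
          else if (leaf_of[i] == nd.right) { sr += r[i]; ++nr; }
        }
        double log_lik = leaf_loglik(sl + sr, nl + nr, sigma2, smu2) -
                         leaf_loglik(sl, nl, sigma2, smu2) -
                         leaf_loglik(sr, nr, sigma2, smu2);
        int d = nd.depth;
        double lp_split = log_split_prob(d, alpha_t, beta_t);
        double lp_nosplit = std::log(1.0 - std::exp(lp_split));
        double lp_child_nosplit =
            2.0 * std::log(1.0 - std::exp(log_split_prob(d + 1, alpha_t, beta_t)));
        double log_prior = lp_nosplit - lp_split - lp_child_nosplit +
                           std::log((double)p) +
                           std::log((double)cuts[nd.var].n_elem);
        int n_leaves_after = (int)tr.leaves().size() - 1;
        double log_prop =
            std::log((double)nogs.size()) -
            std::log((double)n_leaves_after) - std::log((double)p) -
            std::log((double)cuts[nd.var].n_elem);
        // a reverse grow from a stump is proposed with probability 1
        if (n_leaves_after == 1) log_prop += std::log(2.0);
        double log_alpha = log_lik + log_prior + log_prop;
        if (std::log(R::runif(0.0, 1.0)) < log_alpha) {
          tr.nodes[nd.left].active = false;
          tr.nodes[nd.right].active = false;
          nd.leaf = true; nd.var = -1; nd.cut = -1;
          nd.left = -1; nd.right = -1;
        }
      }

      // draw leaf values and refresh the tree's fit
      for (int i = 0; i < n; ++i) leaf_of[i] = tr.locate(X.row(i), cuts);
      stat.clear();
      for (int i = 0; i < n; ++i) {
        auto& s = stat[leaf_of[i]];
        s.first += r[i]; s.second += 1;
      }
      for (auto& kv : stat) {
        double denom = sigma2 + kv.second.second * smu2;
        double mean = smu2 * kv.second.first / denom;
        double sdv = std::sqrt(sigma2 * smu2 / denom);
        tr.nodes[kv.first].mu = R::rnorm(mean, sdv);
      }
      arma::vec newfit(n);
      for (int i = 0; i < n; ++i) newfit[i] = tr.nodes[leaf_of[i]].mu;
      total_fit += newfit - fits.col(t);
      fits.col(t) = newfit;
      if (!total_fit.is_finite()) stop("non-finite fit at iteration %d", iter + 1);
    }

    if (!binary) {
      arma::vec e = z - total_fit;
      double ss = arma::dot(e, e);
      sigma2 = (nu * lambda_s + ss) / R::rchisq(nu + n);
    }

    if (iter >= n_burn) {
      int d = iter - n_burn;
      for (int t = 0; t < n_trees; ++t)
        for (const Node& nd : trees[t].nodes)
          if (nd.active && !nd.leaf) varcount(d, nd.var) += 1;
      sigma_draws[d] = std::sqrt(sigma2);
    }
  }

  return Rcpp::List::create(Rcpp::Named("varcount") = varcount,
                            Rcpp::Named("sigma") = sigma_draws);
}
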