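#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Probit Bayesian additive regression trees (sum-of-trees binary
// classifier, Albert-Chib latent-variable augmentation).
//
//   z_i ~ N(offset + sum_t g(x_i; T_t, M_t), 1), y_i = 1{z_i > 0}
//   leaf values mu ~ N(0, s2mu), s2mu = (3 / (k sqrt(m)))^2
//   tree depth prior: p(split at depth d) = alpha (1 + d)^-beta
//
// Structural moves: grow / prune with Metropolis-Hastings, integrated
// leaf likelihoods.  All randomness from R's RNG (seed on the R side).

namespace {

struct Tree {
  // node arrays; leaf iff left < 0
  std::vector<int> var, cut, left, right, parent;
  std::vector<double> mu;
  void stump() {
    var.assign(1, -1); cut.assign(1, -1);
    left.assign(1, -1); right.assign(1, -1);
    parent.assign(1, -1); mu.assign(1, 0.0);
  }
  int addNode(int par) {
    var.push_back(-1); cut.push_back(-1);
    left.push_back(-1); right.push_back(-1);
    parent.push_back(par); mu.push_back(0.0);
    return (int) var.size() - 1;
  }
  bool isLeaf(int id) const { return left[id] < 0; }
  int depth(int id) const {
    int d = 0;
    while (parent[id] >= 0) { id = parent[id]; ++d; }
    return d;
  }
  // drop nodes unreachable from the root (after a prune)
  void compact() {
    const int m = (int) var.size();
    std::vector<int> remap(m, -1), order;
    order.push_back(0);
    for (size_t q = 0; q < order.size(); ++q) {
      const int id = order[q];
      if (!isLeaf(id)) {
        order.push_back(left[id]);
        order.push_back(right[id]);
      }
    }
    for (size_t q = 0; q < order.size(); ++q) remap[order[q]] = (int) q;
    Tree out;
    out.var.resize(order.size()); out.cut.resize(order.size());
    out.left.resize(order.size()); out.right.resize(order.size());
    out.parent.resize(order.size()); out.mu.resize(order.size());
    for (size_t q = 0; q < order.size(); ++q) {
      const int id = order[q];
      out.var[q] = var[id]; out.cut[q] = cut[id]; out.mu[q] = mu[id];
      out.left[q] = left[id] < 0 ? -1 : remap[left[id]];
      out.right[q] = right[id] < 0 ? -1 : remap[right[id]];
      out.parent[q] = parent[id] < 0 ? -1 : remap[parent[id]];
    }
    *this = out;
  }
};

// leaf id for one observation
int leafOf(const Tree &t, const NumericMatrix &X,
           const std::vector<std::vector<double> > &cuts, int i) {
  int id = 0;
  while (!t.isLeaf(id))
    id = X(i, t.var[id]) <= cuts[t.var[id]][t.cut[id]]
       ? t.left[id] : t.right[id];
  return id;
}

double logNodeLik(double n, double s, double s2mu) {
  const double d = 1.0 + n * s2mu;
  return -0.5 * std::log(d) + 0.5 * s2mu * s * s / d;
}

double psplit(int d, double alpha, double beta) {
  return alpha * std::pow(1.0 + d, -beta);
}

} // namespace

// [[Rcpp::export(name = ".bart_probit_fit")]]
List bart_probit_fit(NumericMatrix X, IntegerVector y, int nTrees,
                     int nDraws, int burn, int keepEvery,
                     double alpha, double beta, double kFactor,
                     int numCut) {
  const int n = X.nrow(), p = X.ncol();
  const double s2mu = std::pow(3.0 / (kFactor * std::sqrt((double) nTrees)), 2);

  // cutpoint grids: uniform over each predictor's observed range
  std::vector<std::vector<double> > cuts(p);
  for (int j = 0; j < p; ++j) {
    double lo = X(0, j), hi = X(0, j);
    for (int i = 1; i < n; ++i) {
      if (X(i, j) < lo) lo = X(i, j);
      if (X(i, j) > hi) hi = X(i, j);
    }
    cuts[j].resize(numCut);
    for (int c = 0; c < numCut; ++c)
      cuts[j][c] = lo + (c + 1.0) * (hi - lo) / (numCut + 1.0);
  }

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  if (ybar < 1e-3) ybar = 1e-3;
  if (ybar > 1 - 1e-3) ybar = 1 - 1e-3;
  const double offset = R::qnorm(ybar, 0.0, 1.0, 1, 0);

  std::vector<Tree> trees(nTrees);
  for (int t = 0; t < nTrees; ++t) trees[t].stump();

  std::vector<double> fhat(n, 0.0), z(n), resid(n), gcur(n);
  for (int i = 0; i < n; ++i) z[i] = y[i] ? 0.5 : -0.5;

  const int total = burn + nDraws;
  NumericVector importance(p);
  std::vector<double> varProp(p);
  List forests;
  std::vector<int> leafIdx(n), obsBuf;

  for (int it = 0; it < total; ++it) {
    for (int t = 0; t < nTrees; ++t) {
      Tree &tr = trees[t];
      // partial residual: z - offset - (fhat - this tree's fit)
      for (int i = 0; i < n; ++i) {
        leafIdx[i] = leafOf(tr, X, cuts, i);
        gcur[i] = tr.mu[leafIdx[i]];
        resid[i] = z[i] - offset - (fhat[i] - gcur[i]);
      }

      // collect leaves and prunable (both-children-leaf) internals
      std::vector<int> leaves, prunable;
      for (int id = 0; id < (int) tr.var.size(); ++id) {
        if (tr.isLeaf(id)) leaves.push_back(id);
        else if (tr.isLeaf(tr.left[id]) && tr.isLeaf(tr.right[id]))
          prunable.push_back(id);
      }
      const bool isStump = tr.var.size() == 1;
      const double pGrow = isStump ? 1.0 : 0.5;

      if (unif_rand() < pGrow) {
        // GROW: split a uniformly chosen leaf
        const int L = (int) leaves.size();
        const int leaf = leaves[(int) (unif_rand() * L) % L];
        const int v = (int) (unif_rand() * p) % p;
        const int c = (int) (unif_rand() * numCut) % numCut;
        double nl = 0, nr = 0, sl = 0, sr = 0, nn = 0, sn = 0;
        for (int i = 0; i < n; ++i) if (leafIdx[i] == leaf) {
          nn += 1; sn += resid[i];
          if (X(i, v) <= cuts[v][c]) { nl += 1; sl += resid[i]; }
          else { nr += 1; sr += resid[i]; }
        }
        if (nl > 0 && nr > 0) {
          const int d = tr.depth(leaf);
          const double ps = psplit(d, alpha, beta);
          const double ps1 = psplit(d + 1, alpha, beta);
          // prunable count after the grow: the new internal node is
          // prunable; the leaf's parent (if it was) no longer is
          int w2new = 1;
          for (size_t q = 0; q < prunable.size(); ++q)
            if (prunable[q] != tr.parent[leaf]) ++w2new;
          const double pPruneNew = 0.5;
          double logA =
            logNodeLik(nl, sl, s2mu) + logNodeLik(nr, sr, s2mu) -
            logNodeLik(nn, sn, s2mu) +
            std::log(ps) + 2.0 * std::log(1.0 - ps1) -
            std::log(1.0 - ps) +
            std::log(pPruneNew) - std::log(pGrow) +
            std::log((double) L) - std::log((double) w2new);
          if (std::log(unif_rand()) < logA) {
            const int lid = tr.addNode(leaf);
            const int rid = tr.addNode(leaf);
            tr.var[leaf] = v; tr.cut[leaf] = c;
            tr.left[leaf] = lid; tr.right[leaf] = rid;
          }
        }
      } else if (!prunable.empty()) {
        // PRUNE: collapse a uniformly chosen both-leaf internal
        const int W = (int) prunable.size();
        const int node = prunable[(int) (unif_rand() * W) % W];
        double nl = 0, nr = 0, sl = 0, sr = 0;
        for (int i = 0; i < n; ++i) {
          if (leafIdx[i] == tr.left[node]) { nl += 1; sl += resid[i]; }
          else if (leafIdx[i] == tr.right[node]) { nr += 1; sr += resid[i]; }
        }
        const int d = tr.depth(node);
        const double ps = psplit(d, alpha, beta);
        const double ps1 = psplit(d + 1, alpha, beta);
        int L = 0;
        for (int id = 0; id < (int) tr.var.size(); ++id)
          if (tr.isLeaf(id)) ++L;
        const int Lnew = L - 1;   // leaves after pruning
        const bool becomesStump = tr.var.size() == 3;
        const double pGrowNew = becomesStump ? 1.0 : 0.5;
        double logA =
          logNodeLik(nl + nr, sl + sr, s2mu) -
          logNodeLik(nl, sl, s2mu) - logNodeLik(nr, sr, s2mu) -
          std::log(ps) - 2.0 * std::log(1.0 - ps1) +
          std::log(1.0 - ps) +
          std::log(pGrowNew) - std::log(0.5) +
          std::log((double) W) - std::log((double) Lnew);
        if (std::log(unif_rand()) < logA) {
          tr.left[node] = -1; tr.right[node] = -1;
          tr.var[node] = -1; tr.cut[node] = -1;
          tr.compact();
        }
      }

      // sample leaf values and refresh the tree's fit
      std::vector<double> cnt(tr.var.size(), 0.0), sum(tr.var.size(), 0.0);
      for (int i = 0; i < n; ++i) {
        leafIdx[i] = leafOf(tr, X, cuts, i);
        cnt[leafIdx[i]] += 1;
        sum[leafIdx[i]] += resid[i];
      }
      for (int id = 0; id < (int) tr.var.size(); ++id)
        if (tr.isLeaf(id)) {
          const double post = 1.0 + cnt[id] * s2mu;
          tr.mu[id] = s2mu * sum[id] / post +
            std::sqrt(s2mu / post) * norm_rand();
        }
      for (int i = 0; i < n; ++i) {
        const double gnew = tr.mu[leafIdx[i]];
        fhat[i] += gnew - gcur[i];
      }
    }

    // latent z | f, y  (truncated normal)
    for (int i = 0; i < n; ++i) {
      const double m = offset + fhat[i];
      const double a = R::pnorm(-m, 0.0, 1.0, 1, 0);
      double u = unif_rand(), P;
      if (y[i] == 1) P = a + u * (1.0 - a); else P = u * a;
      if (P < 1e-12) P = 1e-12;
      if (P > 1.0 - 1e-12) P = 1.0 - 1e-12;
      z[i] = m + R::qnorm(P, 0.0, 1.0, 1, 0);
    }

    if (it >= burn) {
      // splitting-rule proportions for this draw
      std::fill(varProp.begin(), varProp.end(), 0.0);
      int nSplit = 0;
      for (int t = 0; t < nTrees; ++t) {
        const Tree &tr = trees[t];
        for (int id = 0; id < (int) tr.var.size(); ++id)
          if (!tr.isLeaf(id)) { varProp[tr.var[id]] += 1; ++nSplit; }
      }
      if (nSplit > 0)
        for (int j = 0; j < p; ++j) importance[j] += varProp[j] / nSplit;
      else
        for (int j = 0; j < p; ++j) importance[j] += 1.0 / p;

      if ((it - burn) % keepEvery == 0) {
        List draw(nTrees);
        for (int t = 0; t < nTrees; ++t) {
          const Tree &tr = trees[t];
          const int nn = (int) tr.var.size();
          NumericMatrix M(nn, 5);
          for (int id = 0; id < nn; ++id) {
            M(id, 0) = tr.var[id];
            M(id, 1) = tr.var[id] >= 0 ? cuts[tr.var[id]][tr.cut[id]] : NA_REAL;
            M(id, 2) = tr.left[id];
            M(id, 3) = tr.right[id];
            M(id, 4) = tr.mu[id];
          }
          draw[t] = M;
        }
        forests.push_back(draw);
      }
    }
  }

  for (int j = 0; j < p; ++j) importance[j] /= nDraws;
  return List::create(_["importance"] = importance,
                      _["forests"] = forests,
                      _["offset"] = offset);
}

// [[Rcpp::export(name = ".bart_probit_predict")]]
NumericVector bart_probit_predict(List forests, double offset,
                                  NumericMatrix X) {
  const int n = X.nrow();
  const int nDraw = forests.size();
  NumericVector prob(n);
  for (int d = 0; d < nDraw; ++d) {
    List draw = forests[d];
    for (int i = 0; i < n; ++i) {
      double f = offset;
      for (int t = 0; t < draw.size(); ++t) {
        NumericMatrix M = draw[t];
        int id = 0;
        while (M(id, 0) >= 0)
          id = X(i, (int) M(id, 0)) <= M(id, 1)
             ? (int) M(id, 2) : (int) M(id, 3);
        f += M(id, 4);
      }
      prob[i] += R::pnorm(f, 0.0, 1.0, 1, 0);
    }
  }
  for (int i = 0; i < n; ++i) prob[i] /= nDraw;
  return prob;
}
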