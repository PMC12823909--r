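// GATv2 graph classifier: forward pass and analytic backward pass.
//
// Layer update (per head k): e_ij = a_k . LeakyReLU(Wl_k h_i + Wr_k h_j),
// alpha_ij = softmax_{j in N(i)} e_ij, out_i = sum_j alpha_ij Wr_k h_j.
// Neighborhoods always include a self-loop. Intermediate layers concatenate
// the K heads and apply Mish; the final layer averages heads without
// activation. Readout: scalar projection + softmax over nodes + weighted
// sum; then an MLP head with Mish hidden layers and a sigmoid output.
//
// Dropout (training only): edge dropout re-drawn independently per layer;
// node dropout zeroes whole node vectors (inverted scaling 1/(1-p)) on each
// layer's input. Randomness comes from R's RNG so set.seed() governs it.
//
// Layout: everything is column-major-friendly — node representations are
// d x n (one column per node), per-edge quantities KF x m (one column per
// directed edge, head k owning rows k*F .. (k+1)*F-1), with the directed
// edge list sorted by target node (CSR, self-loop first) so per-target
// ranges are contiguous column blocks.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// mish(x) = x tanh(softplus(x)); with e = exp(x),
// tanh(softplus(x)) = ((1+e)^2 - 1) / ((1+e)^2 + 1) -- one exp() suffices
static inline double mish_(double x) {
    if (x > 20.0) return x;
    const double e = std::exp(x);
    const double w = e * (e + 2.0);
    return x * w / (w + 2.0);
}
static inline double mishd_(double x) {
    if (x > 20.0) return 1.0;
    const double e = std::exp(x);
    const double w = e * (e + 2.0);
    const double t = w / (w + 2.0);
    const double s = e / (1.0 + e);
    return t + x * (1.0 - t * t) * s;
}
static inline double sigmoid_(double x) {
    return x >= 0 ? 1.0 / (1.0 + std::exp(-x))
                  : std::exp(x) / (1.0 + std::exp(x));
}

struct Net {
    int L, K, F, ab, dg;
    double slope;
    vec basis;
    std::vector<mat> Wl, Wr;
    std::vector<vec> att;
    vec Wp;
    std::vector<mat> mW;  // MLP weights (in x out), last has out = 1
    std::vector<vec> mb;
};

static Net parse_net(const List& params, const List& config) {
    Net net;
    net.L = as<int>(config["n_layers"]);
    net.K = as<int>(config["n_heads"]);
    net.F = as<int>(config["per_head_dim"]);
    net.ab = as<int>(config["abundance_dim"]);
    net.dg = as<int>(config["genomic_dim"]);
    net.slope = as<double>(config["leaky_slope"]);
    net.basis = as<vec>(params["basis"]);
    List Wl = params["Wl"], Wr = params["Wr"], att = params["att"];
    for (int l = 0; l < net.L; ++l) {
        net.Wl.push_back(as<mat>(Wl[l]));
        net.Wr.push_back(as<mat>(Wr[l]));
        net.att.push_back(as<vec>(att[l]));
    }
    net.Wp = as<vec>(params["Wp"]);
    List mW = params["mlpW"], mb = params["mlpb"];
    for (int j = 0; j < mW.size(); ++j) {
        net.mW.push_back(as<mat>(mW[j]));
        net.mb.push_back(as<vec>(mb[j]));
    }
    return net;
}

struct Grad {
    vec basis;
    std::vector<mat> Wl, Wr;
    std::vector<vec> att;
    vec Wp;
    std::vector<mat> mW;
    std::vector<vec> mb;
    void init(const Net& n) {
        basis.zeros(n.basis.n_elem);
        for (int l = 0; l < n.L; ++l) {
            Wl.push_back(zeros<mat>(n.Wl[l].n_rows, n.Wl[l].n_cols));
            Wr.push_back(zeros<mat>(n.Wr[l].n_rows, n.Wr[l].n_cols));
            att.push_back(zeros<vec>(n.att[l].n_elem));
        }
        Wp.zeros(n.Wp.n_elem);
        for (size_t j = 0; j < n.mW.size(); ++j) {
            mW.push_back(zeros<mat>(n.mW[j].n_rows, n.mW[j].n_cols));
            mb.push_back(zeros<vec>(n.mb[j].n_elem));
        }
    }
};

struct LayerCache {
    mat Hin, Zl, Zr, U, alpha, OutPre;  // Hin d x n; U KF x m; alpha K x m
    vec mask;
    uvec tgt, src;
    std::vector<int> start;  // CSR offsets by target node
};

struct FwdCache {
    std::vector<LayerCache> layers;
    mat H0, Hfin;            // d x n; F x n
    vec A, hhat, P;
    std::vector<vec> mlp_x, mlp_pre;
    double logit, prob;
};

// directed edges grouped by target (self-loop first), optional edge dropout
static void build_csr(int n, const imat& und, bool training, double pe,
                      LayerCache& lc) {
    std::vector<std::vector<int>> adj(n);
    for (uword e = 0; e < und.n_rows; ++e) {
        int i = und(e, 0) - 1, j = und(e, 1) - 1;
        if (training && pe > 0 && unif_rand() < pe) continue;
        adj[i].push_back(j);
        adj[j].push_back(i);
    }
    lc.start.assign(n + 1, 0);
    for (int t = 0; t < n; ++t)
        lc.start[t + 1] = lc.start[t] + 1 + (int)adj[t].size();
    const int m = lc.start[n];
    lc.tgt.set_size(m);
    lc.src.set_size(m);
    for (int t = 0; t < n; ++t) {
        int p = lc.start[t];
        lc.tgt(p) = t; lc.src(p) = t; ++p;  // self-loop
        for (int j : adj[t]) { lc.tgt(p) = t; lc.src(p) = j; ++p; }
    }
}

// genomic_t comes in transposed (d_g x n)
static void forward_graph(const Net& net, const vec& abund,
                          const mat& genomic_t, const imat& und,
                          bool training, double pe, double pn, FwdCache& fc) {
    const int n = abund.n_elem, K = net.K, F = net.F, KF = K * F;
    fc.H0.set_size(net.ab + net.dg, n);
    for (int i = 0; i < n; ++i) {
        fc.H0.col(i).head(net.ab) = abund(i) * net.basis;
        if (net.dg > 0) fc.H0.col(i).tail(net.dg) = genomic_t.col(i);
    }
    mat H = fc.H0;
    fc.layers.assign(net.L, LayerCache());
    for (int l = 0; l < net.L; ++l) {
        LayerCache& lc = fc.layers[l];
        lc.mask.ones(n);
        if (training && pn > 0)
            for (int i = 0; i < n; ++i)
                lc.mask(i) = (unif_rand() < pn) ? 0.0 : 1.0 / (1.0 - pn);
        lc.Hin = H;
        if (training && pn > 0)
            for (int i = 0; i < n; ++i) lc.Hin.col(i) *= lc.mask(i);
        build_csr(n, und, training, pe, lc);
        const int m = lc.tgt.n_elem;
        lc.Zl = net.Wl[l].t() * lc.Hin;    // KF x n
        lc.Zr = net.Wr[l].t() * lc.Hin;
        lc.U = lc.Zl.cols(lc.tgt) + lc.Zr.cols(lc.src);  // KF x m
        mat V = lc.U;
        V.transform([&](double x) { return x > 0 ? x : net.slope * x; });
        // attention logits S(k,e) = a_block_k . V_block_k(:,e)
        mat Va = V.each_col() % net.att[l];
        mat S(K, m);
        for (int k = 0; k < K; ++k)
            S.row(k) = sum(Va.rows(k * F, (k + 1) * F - 1), 0);
        lc.alpha.set_size(K, m);
        for (int t = 0; t < n; ++t) {
            const int a = lc.start[t], b = lc.start[t + 1];
            for (int k = 0; k < K; ++k) {
                double mx = -datum::inf;
                for (int e = a; e < b; ++e) mx = std::max(mx, S.at(k, e));
                double tot = 0;
                for (int e = a; e < b; ++e) {
                    lc.alpha.at(k, e) = std::exp(S.at(k, e) - mx);
                    tot += lc.alpha.at(k, e);
                }
                for (int e = a; e < b; ++e) lc.alpha.at(k, e) /= tot;
            }
        }
        // weighted messages M(:,e) = alpha-block-scaled Zr(:, src(e))
        mat M(KF, m);
        for (int e = 0; e < m; ++e) {
            const double* zs = lc.Zr.colptr(lc.src(e));
            double* me = M.colptr(e);
            for (int k = 0; k < K; ++k) {
                const double a_ = lc.alpha.at(k, e);
                for (int f = 0; f < F; ++f)
                    me[k * F + f] = a_ * zs[k * F + f];
            }
        }
        lc.OutPre.set_size(KF, n);
        for (int t = 0; t < n; ++t)
            lc.OutPre.col(t) = sum(M.cols(lc.start[t], lc.start[t + 1] - 1), 1);
        if (l < net.L - 1) {
            H = lc.OutPre;
            H.transform([](double x) { return mish_(x); });
        } else {
            fc.Hfin.zeros(F, n);
            for (int k = 0; k < K; ++k)
                fc.Hfin += lc.OutPre.rows(k * F, (k + 1) * F - 1);
            fc.Hfin /= (double)K;
        }
    }
    // attention readout
    fc.hhat = fc.Hfin.t() * net.Wp;
    fc.A = exp(fc.hhat - fc.hhat.max());
    fc.A /= accu(fc.A);
    fc.P = fc.Hfin * fc.A;
    // MLP head
    fc.mlp_x.clear(); fc.mlp_pre.clear();
    vec x = fc.P;
    const int nlay = (int)net.mW.size();
    for (int j = 0; j < nlay; ++j) {
        fc.mlp_x.push_back(x);
        vec pre = net.mW[j].t() * x + net.mb[j];
        fc.mlp_pre.push_back(pre);
        if (j < nlay - 1) {
            x = pre;
            x.transform([](double v) { return mish_(v); });
        } else {
            fc.logit = pre(0);
        }
    }
    fc.prob = sigmoid_(fc.logit);
}

// backward for one graph; dlogit = d loss / d logit; accumulates into g
static void backward_graph(const Net& net, const vec& abund, FwdCache& fc,
                           double dlogit, Grad& g) {
    const int K = net.K, F = net.F, KF = K * F;
    const int n = fc.A.n_elem;
    // MLP
    const int nlay = (int)net.mW.size();
    vec gx(1); gx(0) = dlogit;
    for (int j = nlay - 1; j >= 0; --j) {
        vec gpre = gx;
        if (j < nlay - 1)
            for (uword q = 0; q < gpre.n_elem; ++q)
                gpre(q) *= mishd_(fc.mlp_pre[j](q));
        g.mW[j] += fc.mlp_x[j] * gpre.t();
        g.mb[j] += gpre;
        gx = net.mW[j] * gpre;
    }
    // readout: P = Hfin A; hhat = Hfin' Wp; A = softmax(hhat)
    mat gHfin = gx * fc.A.t();                  // F x n
    vec gA = fc.Hfin.t() * gx;
    vec ghhat = fc.A % (gA - dot(fc.A, gA));
    g.Wp += fc.Hfin * ghhat;
    gHfin += net.Wp * ghhat.t();
    // GAT layers
    mat gH;  // grad wrt the activated output of the previous layer (d x n)
    for (int l = net.L - 1; l >= 0; --l) {
        LayerCache& lc = fc.layers[l];
        const int m = lc.tgt.n_elem;
        mat gOut;
        if (l == net.L - 1) {
            gOut.set_size(KF, n);
            for (int k = 0; k < K; ++k)
                gOut.rows(k * F, (k + 1) * F - 1) = gHfin / (double)K;
        } else {
            gOut = gH;
            for (uword q = 0; q < gOut.n_elem; ++q)
                gOut(q) *= mishd_(lc.OutPre(q));
        }
        mat gZl = zeros<mat>(KF, lc.Zl.n_cols);
        mat gZr = zeros<mat>(KF, lc.Zr.n_cols);
        mat galpha(K, m), gS(K, m);
        for (int e = 0; e < m; ++e) {
            const double* go = gOut.colptr(lc.tgt(e));
            const double* zs = lc.Zr.colptr(lc.src(e));
            double* gz = gZr.colptr(lc.src(e));
            for (int k = 0; k < K; ++k) {
                double acc = 0;
                const double a_ = lc.alpha.at(k, e);
                for (int f = 0; f < F; ++f) {
                    acc += go[k * F + f] * zs[k * F + f];
                    gz[k * F + f] += a_ * go[k * F + f];
                }
                galpha.at(k, e) = acc;
            }
        }
        // softmax backward per (target, head)
        for (int t = 0; t < n; ++t) {
            const int a = lc.start[t], b = lc.start[t + 1];
            for (int k = 0; k < K; ++k) {
                double acc = 0;
                for (int e = a; e < b; ++e)
                    acc += lc.alpha.at(k, e) * galpha.at(k, e);
                for (int e = a; e < b; ++e)
                    gS.at(k, e) = lc.alpha.at(k, e) * (galpha.at(k, e) - acc);
            }
        }
        mat V = lc.U;
        V.transform([&](double x) { return x > 0 ? x : net.slope * x; });
        mat gU(KF, m);
        for (int e = 0; e < m; ++e) {
            const double* ve = V.colptr(e);
            const double* ue = lc.U.colptr(e);
            double* gu = gU.colptr(e);
            for (int k = 0; k < K; ++k) {
                const double gs = gS.at(k, e);
                for (int f = 0; f < F; ++f) {
                    const int q = k * F + f;
                    g.att[l](q) += gs * ve[q];
                    gu[q] = gs * net.att[l](q) * (ue[q] > 0 ? 1.0 : net.slope);
                }
            }
        }
        for (int t = 0; t < n; ++t)
            gZl.col(t) += sum(gU.cols(lc.start[t], lc.start[t + 1] - 1), 1);
        for (int e = 0; e < m; ++e) gZr.col(lc.src(e)) += gU.col(e);
        g.Wl[l] += lc.Hin * gZl.t();
        g.Wr[l] += lc.Hin * gZr.t();
        mat gHin = net.Wl[l] * gZl + net.Wr[l] * gZr;  // d x n
        for (uword i = 0; i < gHin.n_cols; ++i) gHin.col(i) *= lc.mask(i);
        gH = gHin;
    }
    // layer 0 features: grad wrt the shared abundance basis
    g.basis += gH.rows(0, net.ab - 1) * abund;
}

static void parse_graph(const List& graph, vec& abund, mat& genomic_t,
                        imat& und, int dg) {
    abund = as<vec>(graph["abund"]);
    if (dg > 0) genomic_t = as<mat>(graph["genomic_t"]);
    else genomic_t.set_size(0, abund.n_elem);
    und = as<imat>(graph["edges"]);
}

//' @noRd
// [[Rcpp::export(name = ".gatForwardCpp")]]
List gat_forward_cpp(List params, List config, List graph) {
    Net net = parse_net(params, config);
    vec abund; mat genomic_t; imat und;
    parse_graph(graph, abund, genomic_t, und, net.dg);
    FwdCache fc;
    forward_graph(net, abund, genomic_t, und, false, 0.0, 0.0, fc);
    return List::create(
        _["prob"] = fc.prob,
        _["attention"] = NumericVector(fc.A.begin(), fc.A.end()),
        _["importance"] = NumericVector(fc.hhat.begin(), fc.hhat.end()),
        _["pooled"] = NumericVector(fc.P.begin(), fc.P.end()),
        _["node_embed"] = mat(fc.Hfin.t()));
}

//' @noRd
// [[Rcpp::export(name = ".gatBatchCpp")]]
List gat_batch_cpp(List params, List config, List graphs, NumericVector labels,
                   bool training, bool want_grad) {
    Net net = parse_net(params, config);
    const double pe = as<double>(config["edge_dropout"]);
    const double pn = as<double>(config["node_dropout"]);
    const int B = graphs.size();
    Grad g;
    if (want_grad) g.init(net);
    double loss = 0;
    NumericVector probs(B);
    for (int b = 0; b < B; ++b) {
        vec abund; mat genomic_t; imat und;
        parse_graph(graphs[b], abund, genomic_t, und, net.dg);
        FwdCache fc;
        forward_graph(net, abund, genomic_t, und, training, pe, pn, fc);
        probs[b] = fc.prob;
        const double y = labels[b];
        const double eps = 1e-12;
        loss += -(y * std::log(fc.prob + eps) +
                  (1 - y) * std::log(1 - fc.prob + eps));
        if (want_grad) backward_graph(net, abund, fc, (fc.prob - y) / B, g);
    }
    loss /= B;
    List out = List::create(_["loss"] = loss, _["probs"] = probs);
    if (want_grad) {
        List Wl(net.L), Wr(net.L), att(net.L);
        for (int l = 0; l < net.L; ++l) {
            Wl[l] = g.Wl[l]; Wr[l] = g.Wr[l];
            att[l] = NumericVector(g.att[l].begin(), g.att[l].end());
        }
        List mW(g.mW.size()), mb(g.mb.size());
        for (size_t j = 0; j < g.mW.size(); ++j) {
            mW[j] = g.mW[j];
            mb[j] = NumericVector(g.mb[j].begin(), g.mb[j].end());
        }
        out["grads"] = List::create(
            _["basis"] = NumericVector(g.basis.begin(), g.basis.end()),
            _["Wl"] = Wl, _["Wr"] = Wr, _["att"] = att,
            _["Wp"] = NumericVector(g.Wp.begin(), g.Wp.end()),
            _["mlpW"] = mW, _["mlpb"] = mb);
    }
    return out;
}
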