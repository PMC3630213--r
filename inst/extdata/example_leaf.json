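{"leaf_id":"example1","genotype":"wt","frame":{"origin_x_px":39,"origin_y_px":4,"tip_x_px":39,"tip_y_px":74},"trichomes":[{"trichome_id":1,"class":1,"x_px":33.8977454532869,"y_px":18.6156977787614},{"trichome_id":2,"class":1,"x_px":42.7437493905891,"y_px":7.29201042582281},{"trichome_id":3,"class":1,"x_px":61.4720625006594,"y_px":22.665855484549},{"trichome_id":4,"class":2,"x_px":51.7314771017991,"y_px":24.2728119457606},{"trichome_id":5,"class":2,"x_px":18.9534477700945,"y_px":33.5847007129341},{"trichome_id":6,"class":2,"x_px":48.7952232353855,"y_px":33.496703693876},{"trichome_id":7,"class":3,"x_px":62.5656457394361,"y_px":52.1270387584809},{"trichome_id":8,"class":3,"x_px":17.8622208475135,"y_px":59.179993461119},{"trichome_id":9,"class":4,"x_px":33.3470243921038,"y_px":71.99807613343},{"trichome_id":10,"class":4,"x_px":49.3384638719726,"y_px":67.9569038648624}]}
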